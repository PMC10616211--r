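#' One-site total-plus-nonspecific binding model
#'
#' `Y = Bmax * X / (Kd + X) + NS * X + B0`: hyperbolic specific binding with
#' dissociation constant `Kd`, a linear nonspecific component with slope
#' `NS`, and a constant background `B0` (included because plate blanks are
#' subtracted imperfectly; set to 0 to recover the bare two-component
#' model).
#'
#' @param X ligand concentrations (nM, >= 0).
#' @param Kd dissociation constant (nM, > 0).
#' @param Bmax maximal specific binding (signal units).
#' @param NS nonspecific slope (signal per nM).
#' @param B0 background signal (default 0).
#' @return model signal at each `X`.
#' @export
total_binding <- function(X, Kd, Bmax, NS = 0, B0 = 0) {
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  stopifnot(all(X >= 0))
  Bmax * X / (Kd + X) + NS * X + B0
}

#' A concentration-signal binding curve
#'
#' @param X concentrations (nM, >= 0); duplicates mark replicates.
#' @param Y signals (e.g. absorbance units), same length as `X`.
#' @param replicate optional replicate labels.
#' @return data.frame of class `binding_curve`.
#' @export
binding_curve <- function(X, Y, replicate = NULL) {
  stopifnot(length(X) == length(Y), all(X >= 0))
  d <- data.frame(X = as.numeric(X), Y = as.numeric(Y),
                  replicate = if (is.null(replicate)) 1L else replicate)
  class(d) <- c("binding_curve", "data.frame")
  d
}

#' Subtract plate background from a binding curve
#'
#' Subtracts the mean of blank-well signals (wells with no immobilised
#' partner) from every signal.
#'
#' @param curve a `binding_curve`.
#' @param blank_signals numeric vector of blank-well readings.
#' @return corrected `binding_curve`.
#' @export
subtract_background <- function(curve, blank_signals) {
  if (length(blank_signals) == 0L) stop("no blank signals", call. = FALSE)
  curve$Y <- curve$Y - mean(blank_signals)
  curve
}

#' Fit the one-site total-plus-nonspecific model
#'
#' Nonlinear least squares over (Kd, Bmax, NS, B0) with positivity of Kd
#' enforced by fitting log(Kd), and Bmax, NS bounded below at 0
#' (Levenberg-Marquardt). Standard errors come from the Jacobian at the
#' optimum; the Kd standard error is delta-method-propagated from log(Kd).
#' Initialisation: Kd0 is the concentration nearest the half-range signal,
#' NS0 the slope through the top two concentrations, B00 the minimum
#' signal.
#'
#' @param curve a `binding_curve` (>= 4 distinct concentrations).
#' @param init optional named list overriding initial values
#'   (`Kd`, `Bmax`, `NS`, `B0`).
#' @param fix_B0 logical: fix the background at 0 instead of fitting it.
#' @param weights `"none"` (default) or `"1/Y2"`.
#' @return list of class `binding_fit`: `Kd`, `Bmax`, `NS`, `B0`, `se`
#'   (named vector), `rss`, `converged`, `unidentifiable` (TRUE when the
#'   curve is flat and Kd is meaningless), and the underlying `fit` object.
#' @export
fit_total_binding <- function(curve, init = NULL, fix_B0 = FALSE,
                              weights = c("none", "1/Y2")) {
  weights <- match.arg(weights)
  X <- curve$X; Y <- curve$Y
  if (length(unique(X)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  rngY <- diff(range(Y))
  xpos <- sort(unique(X[X > 0]))
  # heuristic initial values
  half <- min(Y) + rngY / 2
  Kd0 <- X[which.min(abs(Y - half))]
  if (Kd0 <= 0) Kd0 <- xpos[max(1L, length(xpos) %/% 2L)]
  top2 <- order(X, decreasing = TRUE)[1:2]
  NS0 <- max(0, diff(Y[rev(top2)]) / max(diff(X[rev(top2)]), 1e-12))
  B00 <- if (fix_B0) 0 else min(Y)
  Bmax0 <- max(rngY - NS0 * max(X), 0.1 * rngY, 1e-6)
  if (!is.null(init)) {
    if (!is.null(init$Kd)) Kd0 <- init$Kd
    if (!is.null(init$Bmax)) Bmax0 <- init$Bmax
    if (!is.null(init$NS)) NS0 <- init$NS
    if (!is.null(init$B0)) B00 <- init$B0
  }
  w <- if (weights == "1/Y2") 1 / pmax(Y^2, 1e-12) else rep(1, length(Y))
  dat <- data.frame(X = X, Y = Y)
  fml <- if (fix_B0) Y ~ Bmax * X / (exp(lKd) + X) + NS * X
         else Y ~ Bmax * X / (exp(lKd) + X) + NS * X + B0
  start <- list(lKd = log(Kd0), Bmax = Bmax0, NS = NS0)
  lower <- c(lKd = -Inf, Bmax = 0, NS = 0)
  if (!fix_B0) { start$B0 <- B00; lower <- c(lower, B0 = -Inf) }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start, lower = lower,
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(Kd = Kd0, Bmax = Bmax0, NS = NS0, B0 = B00,
                se = c(Kd = NA_real_, Bmax = NA_real_, NS = NA_real_,
                       B0 = NA_real_),
                rss = sum(w * (Y - total_binding(X, Kd0, Bmax0, NS0, B00))^2),
                converged = FALSE, unidentifiable = TRUE, fit = NULL)
    class(out) <- "binding_fit"
    return(out)
  }
  cf <- coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  ses <- if (is.null(sm)) rep(NA_real_, length(cf)) else sm$coefficients[, "Std. Error"]
  names(ses) <- names(cf)
  Kd <- exp(cf[["lKd"]])
  se <- c(Kd = unname(Kd * ses["lKd"]), Bmax = unname(ses["Bmax"]),
          NS = unname(ses["NS"]),
          B0 = if (fix_B0) 0 else unname(ses["B0"]))
  B0 <- if (fix_B0) 0 else cf[["B0"]]
  rss <- sum(w * residuals(fit)^2)
  # flat curves: Bmax indistinguishable from 0 makes Kd meaningless
  unident <- cf[["Bmax"]] <= max(1e-8, 1e-3 * max(rngY, 1e-12)) ||
    !is.finite(se[["Kd"]])
  out <- list(Kd = Kd, Bmax = cf[["Bmax"]], NS = cf[["NS"]], B0 = B0,
              se = se, rss = rss, converged = TRUE,
              unidentifiable = unident, fit = fit)
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "One-site total+nonspecific fit%s:\n  Kd   %.4g nM (SE %.2g)\n  Bmax %.4g (SE %.2g)\n  NS   %.4g per nM (SE %.2g)\n  B0   %.4g\n",
    if (x$unidentifiable) " [UNIDENTIFIABLE]" else "",
    x$Kd, x$se[["Kd"]], x$Bmax, x$se[["Bmax"]], x$NS, x$se[["NS"]], x$B0))
  invisible(x)
}

#' Cheng-Prusoff conversion of an apparent Kd to a Ki
#'
#' For a competition condition with competitor concentration `L` and
#' competitor's own dissociation constant `Kd_comp`:
#' `Ki = Kd_apparent / (1 + L / Kd_comp)`. Provided for completeness; the
#' apparent Kd itself is the quantity reported by the assay.
#'
#' @param Kd_apparent apparent dissociation constant (nM).
#' @param L competitor concentration (nM).
#' @param Kd_comp competitor dissociation constant (nM).
#' @return Ki in nM.
#' @export
cheng_prusoff_ki <- function(Kd_apparent, L, Kd_comp) {
  Kd_apparent / (1 + L / Kd_comp)
}

#' Read a binding curve from CSV
#'
#' Expected columns: `concentration_nM`, `signal` and optionally
#' `replicate`.
#'
#' @param path CSV path.
#' @return a `binding_curve`.
#' @export
read_binding_curve <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  binding_curve(d$concentration_nM, d$signal,
                replicate = if ("replicate" %in% names(d)) d$replicate else NULL)
}
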