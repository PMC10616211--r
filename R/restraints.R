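#' Cross-link identification records
#'
#' A cross-link names two residues, their expected amino acids (K, C, or
#' `Nterm` for a protein N-terminus) and the linker chemistry that bridged
#' them. Residue chemistry must be compatible with the linker ends:
#' amine-reactive ends pair with lysine or a protein N-terminus,
#' sulfhydryl-reactive ends with cysteine.
#'
#' @param proteinA,proteinB protein names.
#' @param residueA,residueB residue numbers.
#' @param aaA,aaB expected amino acid one-letter codes (`"K"`, `"C"`) or
#'   `"Nterm"`.
#' @param linker linker name as in [builtin_linkers()].
#' @param decoy logical, marks planted false-positive identifications.
#' @return data.frame of class `crosslinks`, one row per link.
#' @export
crosslink <- function(proteinA, residueA, aaA, proteinB, residueB, aaB,
                      linker, decoy = FALSE) {
  links <- data.frame(
    proteinA = as.character(proteinA), residueA = as.integer(residueA),
    aaA = as.character(aaA),
    proteinB = as.character(proteinB), residueB = as.integer(residueB),
    aaB = as.character(aaB),
    linker = as.character(linker),
    decoy = rep_len(as.logical(decoy), length(proteinA)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(links))) check_link_chemistry(links[i, ])
  class(links) <- c("crosslinks", "data.frame")
  links
}

# amine ends react with K or the protein N-terminus; sulfhydryl ends with C.
chem_compatible <- function(aa, chem) {
  if (chem == "amine") aa %in% c("K", "Nterm") else aa == "C"
}

check_link_chemistry <- function(link) {
  lk <- get_linker(link$linker)
  ok <- (chem_compatible(link$aaA, lk$chem_a) &&
           chem_compatible(link$aaB, lk$chem_b)) ||
        (chem_compatible(link$aaA, lk$chem_b) &&
           chem_compatible(link$aaB, lk$chem_a))
  if (!ok)
    stop(sprintf(
      "chemistry mismatch: %s links %s-%s but %s%d is %s and %s%d is %s",
      link$linker, lk$chem_a, lk$chem_b, link$proteinA, link$residueA,
      link$aaA, link$proteinB, link$residueB, link$aaB), call. = FALSE)
  invisible(TRUE)
}

#' Read cross-link identifications from CSV
#'
#' Expected columns: `protein, residue_number, residue_aa, protein2,
#' residue_number2, residue_aa2, linker` and optionally `decoy`.
#'
#' @param path CSV file path.
#' @return a `crosslinks` data.frame.
#' @export
read_crosslinks <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  crosslink(d$protein, d$residue_number, d$residue_aa,
            d$protein2, d$residue_number2, d$residue_aa2, d$linker,
            decoy = if ("decoy" %in% names(d)) d$decoy else FALSE)
}

# The reactive atom of each residue chemistry, with a Calpha fallback for
# models lacking side chains (e.g. bead models); the fallback widens the
# upper bound by `slack` per side.
reactive_atom <- function(aa) {
  switch(aa, K = "NZ", C = "SG", Nterm = "N",
         stop("no reactive-atom convention for ", aa, call. = FALSE))
}

new_restraint <- function(kind, chainA, resA, atomA, chainB, resB, atomB,
                          lower, upper, group) {
  list(kind = kind,
       selA = list(chain = chainA, resno = as.character(resA), atom = atomA),
       selB = list(chain = chainB, resno = as.character(resB), atom = atomB),
       lower = lower, upper = upper, group = group)
}

#' Build unambiguous interaction restraints (UIRs) from cross-links
#'
#' Each cross-link becomes one distance restraint per symmetry-equivalent
#' chain pairing: for a link between protein P (chains in
#' `assembly[[P]]`) and protein Q, every (chain of P, chain of Q)
#' combination receives a copy, tied together by a shared `group` id so
#' evaluation can treat symmetric copies ambiguously. The restraint upper
#' bound is the linker spacer-arm length; the lower bound is 0 (spacer
#' chemistry implies no meaningful minimum). Restraints are measured
#' between reactive atoms (Lys NZ, Cys SG, N-terminal N).
#'
#' @param links a `crosslinks` data.frame.
#' @param assembly named list mapping protein name to the chain ids of its
#'   copies, e.g. `list(DID = c("A","B"), MFN2 = c("C","D"))`.
#' @param correction bound correction in Angstroms carried into violation
#'   reports (default 5).
#' @return list of class `restraints`; attributes keep the correction.
#' @export
uirs_from_crosslinks <- function(links, assembly, correction = 5.0) {
  out <- list()
  if (nrow(links) > 0L) {
    for (i in seq_len(nrow(links))) {
      link <- links[i, ]
      check_link_chemistry(link)
      if (!link$proteinA %in% names(assembly))
        stop("protein not in assembly: ", link$proteinA, call. = FALSE)
      if (!link$proteinB %in% names(assembly))
        stop("protein not in assembly: ", link$proteinB, call. = FALSE)
      lk <- get_linker(link$linker)
      gid <- sprintf("link%02d_%s%d-%s%d_%s", i, link$proteinA, link$residueA,
                     link$proteinB, link$residueB, link$linker)
      for (ca in assembly[[link$proteinA]])
        for (cb in assembly[[link$proteinB]])
          out[[length(out) + 1L]] <- new_restraint(
            "UIR", ca, link$residueA, reactive_atom(link$aaA),
            cb, link$residueB, reactive_atom(link$aaB),
            lower = 0, upper = lk$spacer, group = gid)
    }
  }
  structure(out, class = "restraints", correction = correction)
}

#' Build ambiguous interaction restraints (AIRs) from active residues
#'
#' One AIR is created per active residue of side A, anchored against the
#' union of all active-residue atoms of side B, and evaluated with the
#' r^-6-pooled effective distance. This is the standard way to express
#' "this residue is at the interface" without committing to a partner.
#'
#' @param activesA data.frame with columns `chain`, `resno` (A-side anchors).
#' @param activesB data.frame with columns `chain`, `resno` (B-side pool).
#' @param upper effective-distance upper bound in Angstroms (default 2.0,
#'   the convention of ambiguity-driven docking).
#' @param correction bound correction (default 5).
#' @return list of class `restraints`.
#' @export
airs_from_actives <- function(activesA, activesB, upper = 2.0,
                              correction = 5.0) {
  if (NROW(activesA) == 0L || NROW(activesB) == 0L)
    stop("active-residue lists must be non-empty", call. = FALSE)
  out <- vector("list", NROW(activesA))
  for (i in seq_len(NROW(activesA))) {
    out[[i]] <- new_restraint(
      "AIR",
      activesA$chain[i], activesA$resno[i], NA_character_,
      activesB$chain, activesB$resno, NA_character_,
      lower = 0, upper = upper,
      group = sprintf("air%02d_%s:%s", i, activesA$chain[i], activesA$resno[i]))
  }
  structure(out, class = "restraints", correction = correction)
}

#' @export
print.restraints <- function(x, ...) {
  cat(sprintf("%d distance restraint(s): %d UIR, %d AIR\n", length(x),
              sum(vapply(x, function(r) r$kind == "UIR", TRUE)),
              sum(vapply(x, function(r) r$kind == "AIR", TRUE))))
  invisible(x)
}

#' Effective (r^-6-pooled) distance between two atom groups
#'
#' `(sum over all cross pairs d_ij^-6)^(-1/6)`; the soft-minimum used to
#' evaluate ambiguous restraints. Always less than or equal to the minimum
#' pair distance.
#'
#' @param a,b coordinate matrices (n x 3, m x 3).
#' @return effective distance in Angstroms.
#' @export
effective_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty group", call. = FALSE)
  d <- cross_dist(a, b)
  sum(d^(-6))^(-1 / 6)
}

# Resolve one side of a restraint to atom indices. UIR sides name a single
# reactive atom; if absent (side-chain-free models) fall back to CA and
# report the per-side slack to be added to the upper bound.
resolve_restraint_side <- function(structure, side, kind, fallback_slack = 1.0) {
  if (kind == "AIR" || is.na(side$atom[1L])) {
    idx <- unlist(lapply(seq_along(side$chain), function(i)
      atom_select(structure, chain = side$chain[i], resno = side$resno[i])))
    return(list(idx = idx, slack = 0))
  }
  idx <- atom_select(structure, chain = side$chain, resno = side$resno,
                     elety = side$atom)
  if (length(idx) > 0L) return(list(idx = idx, slack = 0))
  idx <- atom_select(structure, chain = side$chain, resno = side$resno,
                     elety = "CA")
  list(idx = idx, slack = fallback_slack)
}

#' Evaluate distance restraints against assembly coordinates
#'
#' UIRs are measured as the minimum reactive-atom distance, AIRs as the
#' r^-6 effective distance. The violation of a restraint is
#' `max(0, d - upper, lower - d)` and the restraint is "followed" iff its
#' violation is at or below the bound `correction` (inclusive), the
#' tolerance convention of restraint-driven docking. With
#' `group_mode = "min"` symmetry-equivalent copies sharing a `group` are
#' scored by the copy with the smallest violation (a link is satisfied if
#' any symmetric pairing satisfies it); the default `"each"` lists and
#' counts every copy separately.
#'
#' @param structure a `tstruct` holding the assembly.
#' @param restraints a `restraints` list.
#' @param correction bound correction in Angstroms (default 5.0).
#' @param group_mode `"each"` or `"min"`.
#' @param fallback_slack Angstroms added to the upper bound per side when a
#'   named reactive atom is absent and CA is used instead (default 1).
#' @return list of class `violation_report`: `table` (per-restraint
#'   data.frame with `id`, `group`, `kind`, `distance`, `upper`,
#'   `violation`, `followed`), `n_total`, `n_followed`, `correction`.
#' @export
evaluate_restraints <- function(structure, restraints, correction = 5.0,
                                group_mode = c("each", "min"),
                                fallback_slack = 1.0) {
  group_mode <- match.arg(group_mode)
  rows <- lapply(seq_along(restraints), function(i) {
    r <- restraints[[i]]
    sa <- resolve_restraint_side(structure, r$selA, r$kind, fallback_slack)
    sb <- resolve_restraint_side(structure, r$selB, r$kind, fallback_slack)
    if (length(sa$idx) == 0L || length(sb$idx) == 0L)
      stop("unresolvable selection in restraint ", r$group, call. = FALSE)
    a <- coords(structure, sa$idx); b <- coords(structure, sb$idx)
    d <- if (r$kind == "AIR") effective_distance(a, b) else min(cross_dist(a, b))
    upper <- r$upper + sa$slack + sb$slack
    data.frame(id = i, group = r$group, kind = r$kind, distance = d,
               lower = r$lower, upper = upper,
               violation = max(0, d - upper, r$lower - d),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (group_mode == "min" && nrow(tab) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$group),
                          function(ix) ix[which.min(tab$violation[ix])]))
    tab <- tab[sort(keep), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab$followed <- tab$violation <= correction
  structure(list(table = tab, n_total = nrow(tab),
                 n_followed = sum(tab$followed), correction = correction),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf(
    "%d out of %d distance restraints followed (violation <= %.1f A)\n",
    x$n_followed, x$n_total, x$correction))
  invisible(x)
}

#' Write restraints to a TSV file
#'
#' Dialect: header `kind chainA resA atomA chainB resB atomB lower upper
#' group`; multi-residue AIR sides are comma-joined.
#'
#' @param restraints a `restraints` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  rows <- lapply(restraints, function(r) data.frame(
    kind = r$kind,
    chainA = paste(r$selA$chain, collapse = ","),
    resA = paste(r$selA$resno, collapse = ","),
    atomA = if (is.na(r$selA$atom[1L])) "" else r$selA$atom,
    chainB = paste(r$selB$chain, collapse = ","),
    resB = paste(r$selB$resno, collapse = ","),
    atomB = if (is.na(r$selB$atom[1L])) "" else r$selB$atom,
    lower = r$lower, upper = r$upper, group = r$group,
    stringsAsFactors = FALSE))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read restraints from a TSV file written by [write_restraints()]
#'
#' @param path TSV path.
#' @param correction bound correction attribute (default 5).
#' @return a `restraints` list.
#' @export
read_restraints <- function(path, correction = 5.0) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = list(chainA = "character", chainB = "character",
                                    resA = "character", resB = "character",
                                    atomA = "character", atomB = "character"))
  out <- lapply(seq_len(nrow(d)), function(i) {
    split1 <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]
    new_restraint(d$kind[i],
                  split1(d$chainA[i]), split1(d$resA[i]),
                  if (nzchar(d$atomA[i])) d$atomA[i] else NA_character_,
                  split1(d$chainB[i]), split1(d$resB[i]),
                  if (nzchar(d$atomB[i])) d$atomB[i] else NA_character_,
                  d$lower[i], d$upper[i], d$group[i])
  })
  structure(out, class = "restraints", correction = correction)
}
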