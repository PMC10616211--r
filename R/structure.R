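#' @importFrom stats median optim setNames hclust cutree as.dist coef rnorm runif residuals
#' @importFrom utils head read.csv read.delim write.table
NULL

#' Structure objects
#'
#' A structure is an ordered atom table: one row per atom with chain id,
#' residue number (verbatim from the source file, insertion code appended as
#' a token when present), 3-letter residue name, atom name, element symbol
#' and Cartesian coordinates in Angstroms. It is a plain `data.frame` of
#' class `"tstruct"` so the usual subsetting verbs apply.
#'
#' @param chain,resno,resid,elety,element,x,y,z atom record vectors,
#'   recycled to a common length.
#' @return An object of class `tstruct`.
#' @export
new_structure <- function(chain, resno, resid = "ALA", elety = "CA",
                          element = NULL, x = 0, y = 0, z = 0) {
  n <- max(length(chain), length(resno), length(x), length(y), length(z))
  atoms <- data.frame(
    chain   = rep_len(as.character(chain), n),
    resno   = rep_len(as.character(resno), n),
    resid   = rep_len(as.character(resid), n),
    elety   = rep_len(as.character(elety), n),
    element = rep_len(if (is.null(element))
      guess_element(rep_len(as.character(elety), n)) else as.character(element), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    stringsAsFactors = FALSE
  )
  validate_structure(atoms)
  class(atoms) <- c("tstruct", "data.frame")
  atoms
}

validate_structure <- function(atoms) {
  if (nrow(atoms) < 1L) stop("empty structure: no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records: ",
         paste(head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  invisible(atoms)
}

# Element from atom name: leading letters, standard PDB heuristics (first
# character of 4-letter hydrogen names like 1HB1 is a digit).
guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  e <- sub("[0-9'].*$", "", e)
  two <- toupper(substr(e, 1L, 2L))
  one <- toupper(substr(e, 1L, 1L))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), two, one)
}

#' @export
print.tstruct <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d chain(s) [%s], %d residue(s)\n",
              nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ","),
              nrow(unique(x[, c("chain", "resno")]))))
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure a `tstruct`.
#' @param sel optional integer atom indices.
#' @return numeric matrix with columns x, y, z (Angstroms).
#' @export
coords <- function(structure, sel = NULL) {
  m <- as.matrix(as.data.frame(structure)[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#'
#' @param structure a `tstruct`.
#' @param xyz n x 3 numeric matrix.
#' @return the structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure), ncol(xyz) == 3L)
  structure$x <- xyz[, 1L]; structure$y <- xyz[, 2L]; structure$z <- xyz[, 3L]
  structure
}

#' Select atoms by chain, residue and atom name
#'
#' Resolves a predicate over (chain, residue-number, atom-name) to explicit
#' atom indices. All arguments are optional filters combined with AND;
#' `NULL` means no constraint.
#'
#' @param structure a `tstruct`.
#' @param chain chain id(s).
#' @param resno residue number token(s) (character or integer).
#' @param elety atom name(s).
#' @return integer vector of atom indices (possibly empty).
#' @export
atom_select <- function(structure, chain = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(chain)) keep <- keep & structure$chain %in% as.character(chain)
  if (!is.null(resno)) keep <- keep & structure$resno %in% as.character(resno)
  if (!is.null(elety)) keep <- keep & structure$elety %in% as.character(elety)
  which(keep)
}

#' Parse a selection token
#'
#' Tokens have the form `"chain"`, `"chain:resno"`, `"chain:lo-hi"` or
#' `"chain:resno:atom"`, e.g. `"A:142-380"` or `"B:79:NZ"`.
#'
#' @param structure a `tstruct`.
#' @param token selection string.
#' @return integer vector of atom indices.
#' @export
parse_selection <- function(structure, token) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1L]]
  chain <- parts[1L]
  resno <- NULL
  if (length(parts) >= 2L && nzchar(parts[2L])) {
    r <- parts[2L]
    if (grepl("^-?[0-9]+--?[0-9]+$", r)) {
      lohi <- as.integer(strsplit(sub("(?<=[0-9])-", ";", r, perl = TRUE), ";")[[1L]])
      resno <- seq(lohi[1L], lohi[2L])
    } else resno <- r
  }
  elety <- if (length(parts) >= 3L) parts[3L] else NULL
  atom_select(structure, chain = chain, resno = resno, elety = elety)
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records, preserving chain ids and residue numbering
#' verbatim. Alternate locations are resolved by keeping the
#' highest-occupancy altloc (first on tie); insertion codes are appended to
#' the residue number as a token (e.g. `"100A"`).
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported.
#' @param model model number to read from multi-model files (default 1).
#' @return a `tstruct`.
#' @export
read_structure <- function(path, format = "pdb", model = 1L) {
  if (!identical(format, "pdb")) stop("unsupported format: ", format, call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("empty structure: no atom records in ", path, call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty structure: no atom records in ", path, call. = FALSE)
  nmod <- nrow(pdb$xyz)
  if (model > nmod) stop("model ", model, " not present (file has ", nmod, ")", call. = FALSE)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  # altloc: keep highest occupancy, first on tie
  alt <- at$alt; occ <- at$o
  alt[is.na(alt)] <- ""
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  amb <- which(alt != "")
  if (length(amb)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)[amb]
    for (k in unique(key)) {
      idx <- amb[key == k]
      if (length(idx) > 1L) keep[idx[-which.max(occ[idx])]] <- FALSE
    }
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- " "
  s <- data.frame(
    chain = chain, resno = paste0(at$resno, ins), resid = at$resid,
    elety = at$elety,
    element = if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
      ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy), guess_element(at$elety))
    else guess_element(at$elety),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(s) <- NULL
  validate_structure(s)
  class(s) <- c("tstruct", "data.frame")
  s
}

#' Write a structure as a PDB file
#'
#' Emits PDB v3.3-style ATOM records. When `models` (a list of n x 3
#' coordinate matrices) is given, each coordinate set is wrapped in
#' MODEL/ENDMDL blocks sharing the atom table of `structure`.
#'
#' @param structure a `tstruct`.
#' @param path output file path.
#' @param models optional list of coordinate matrices replacing the
#'   structure's own coordinates, one per MODEL block.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, models = NULL) {
  validate_structure(structure)
  if (nrow(structure) > 99999L)
    stop("PDB format cannot hold more than 99999 atoms", call. = FALSE)
  fmt_one <- function(xyz) {
    resno_num <- sub("[A-Za-z]$", "", structure$resno)
    ins <- ifelse(grepl("[A-Za-z]$", structure$resno),
                  sub("^.*([A-Za-z])$", "\\1", structure$resno), "")
    name4 <- ifelse(nchar(structure$elety) >= 4L,
                    substr(structure$elety, 1L, 4L),
                    sprintf(" %-3s", structure$elety))
    sprintf("ATOM  %5d %s %-3s%2s%4s%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(structure)), name4, structure$resid,
            substr(structure$chain, 1L, 1L), resno_num, ins,
            xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0,
            toupper(substr(structure$element, 1L, 2L)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(models)) {
    writeLines(fmt_one(coords(structure)), con)
  } else {
    for (i in seq_along(models)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(fmt_one(models[[i]]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

cross_dist <- function(a, b) {
  # all-pairs Euclidean distances between rows of a (n x 3) and b (m x 3)
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

resolve_sel <- function(structure, sel) {
  idx <- if (is.numeric(sel)) as.integer(sel)
         else if (is.character(sel) && length(sel) == 1L) parse_selection(structure, sel)
         else stop("selection must be atom indices or a selection token", call. = FALSE)
  if (length(idx) == 0L) stop("empty selection", call. = FALSE)
  idx
}

#' Minimum cross-pair distance between two selections
#'
#' @param structure a `tstruct`.
#' @param selA,selB atom index vectors or selection tokens.
#' @return minimum Euclidean distance over all cross pairs, in Angstroms.
#' @export
min_distance <- function(structure, selA, selB) {
  a <- coords(structure, resolve_sel(structure, selA))
  b <- coords(structure, resolve_sel(structure, selB))
  min(cross_dist(a, b))
}

#' Maximum cross-pair distance between two selections
#'
#' Used to report the span of an assembly, e.g. the longest atom-atom
#' distance between two domains of a docked complex.
#'
#' @inheritParams min_distance
#' @return maximum Euclidean distance over all cross pairs, in Angstroms.
#' @export
max_pair_distance <- function(structure, selA, selB) {
  a <- coords(structure, resolve_sel(structure, selA))
  b <- coords(structure, resolve_sel(structure, selB))
  max(cross_dist(a, b))
}

#' Contact residues of one group against another
#'
#' A residue of group A is reported iff any of its atoms lies within
#' `cutoff` of any atom of group B (inclusive boundary). This is the
#' atom-to-atom 5-Angstrom rule commonly used to call interface residues.
#'
#' @param structure a `tstruct`.
#' @param groupA,groupB disjoint atom index vectors or selection tokens.
#' @param cutoff contact distance in Angstroms (default 5.0).
#' @return data.frame with columns `chain`, `resno`, ordered as in the file.
#' @export
interface_residues <- function(structure, groupA, groupB, cutoff = 5.0) {
  ia <- resolve_sel(structure, groupA)
  ib <- resolve_sel(structure, groupB)
  if (length(intersect(ia, ib)))
    stop("groups must be disjoint", call. = FALSE)
  d <- cross_dist(coords(structure, ia), coords(structure, ib))
  near <- apply(d, 1L, min) <= cutoff
  res <- unique(data.frame(chain = structure$chain[ia][near],
                           resno = structure$resno[ia][near],
                           stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a target point set, using the SVD solution with determinant
#' sign correction so the rotation is always proper (det = +1), including
#' when the unconstrained optimum would be a reflection.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @return list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstroms). Applying
#'   `x %*% t(rotation) + translation` maps mobile onto target.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("point sets must be equal-sized n x 3 matrices", call. = FALSE)
  if (nrow(mobile) < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2L, cm); b <- sweep(target, 2L, ct)
  if (min(svd(a)$d) < 1e-9 && min(svd(b)$d) < 1e-9)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  h <- crossprod(a, b)                       # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.vector(rot %*% cm)
  moved <- tcrossprod(mobile, rot) + matrix(trans, nrow(mobile), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  tcrossprod(as.matrix(xyz), rotation) +
    matrix(translation, nrow(xyz), 3L, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain (unfitted) RMSD; use [superpose()] first for a fitted RMSD.
#'
#' @param a,b equal-sized n x 3 matrices.
#' @return RMSD in Angstroms.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
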