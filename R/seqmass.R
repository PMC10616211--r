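# Amino acid residue masses (residue = amino acid minus water), standard
# monoisotopic and average values, and atom counts for W/Y/C chromophores.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
AA_AVG <- c(
  G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152, V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1140, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099
)
WATER_MONO <- 18.0105646863
WATER_AVG <- 18.0153
CARBAMIDOMETHYL <- 57.02146

# ExPASy/Bjellqvist pKa set used by the "Compute pI" tool.
PK_SIDE <- c(K = 10.00, R = 12.00, H = 5.98, D = 4.05, E = 4.45,
             C = 9.00, Y = 10.00)
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70, G = 7.50)
PK_NTERM_DEFAULT <- 7.50
PK_CTERM <- c(D = 4.55, E = 4.75)
PK_CTERM_DEFAULT <- 3.55

AA_ALPHABET <- names(AA_MONO)

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string", call. = FALSE)
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% AA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", aa[bad[1L]], bad[1L]),
         call. = FALSE)
  aa
}

#' Protein construct definition
#'
#' A named sequence with an optional numbering offset mapping position 1 of
#' the construct to its parent (e.g. UniProt) numbering. Tagged expression
#' constructs keep offset for the parent-derived part via `offset`.
#'
#' @param name construct name.
#' @param sequence 1-letter uppercase amino-acid string.
#' @param offset integer: parent number of position 1 minus 1 (default 0,
#'   i.e. construct numbering).
#' @return list of class `construct`.
#' @export
protein_construct <- function(name, sequence, offset = 0L) {
  check_sequence(sequence)
  structure(list(name = name, sequence = sequence, offset = as.integer(offset)),
            class = "construct")
}

seq_of <- function(x) if (inherits(x, "construct")) x$sequence else x

#' Molecular weight of a protein sequence
#'
#' Sum of residue masses plus one water.
#'
#' @param sequence amino-acid string or a `construct`.
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @export
molecular_weight <- function(sequence, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  aa <- check_sequence(seq_of(sequence))
  if (kind == "average") sum(AA_AVG[aa]) + WATER_AVG
  else sum(AA_MONO[aa]) + WATER_MONO
}

#' Molar extinction coefficient at 280 nm
#'
#' Increment model: 5500 per Trp, 1490 per Tyr, and 125 per cystine
#' (oxidised disulfide-bonded cysteine pair). The reduced convention counts
#' no cysteine contribution; the cystine convention assumes all cysteines
#' are paired (`floor(nC / 2)` cystines).
#'
#' @param sequence amino-acid string or `construct`.
#' @param cystine logical: assume all Cys form cystines (default FALSE).
#' @return extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(sequence, cystine = FALSE) {
  aa <- check_sequence(seq_of(sequence))
  eps <- 5500 * sum(aa == "W") + 1490 * sum(aa == "Y")
  if (cystine) eps <- eps + 125 * (sum(aa == "C") %/% 2L)
  eps
}

# Net charge of a sequence at a given pH under the Bjellqvist pKa model.
charge_at_ph <- function(aa, ph) {
  pos <- function(pk) 1 / (1 + 10^(ph - pk))
  neg <- function(pk) -1 / (1 + 10^(pk - ph))
  nterm_pk <- PK_NTERM[aa[1L]]
  if (is.na(nterm_pk)) nterm_pk <- PK_NTERM_DEFAULT
  cterm_pk <- PK_CTERM[aa[length(aa)]]
  if (is.na(cterm_pk)) cterm_pk <- PK_CTERM_DEFAULT
  q <- pos(nterm_pk) + neg(cterm_pk)
  for (r in c("K", "R", "H")) q <- q + sum(aa == r) * pos(PK_SIDE[r])
  for (r in c("D", "E", "C", "Y")) q <- q + sum(aa == r) * neg(PK_SIDE[r])
  unname(q)
}

#' Isoelectric point of a protein sequence
#'
#' pH at which the net charge under the Bjellqvist fixed-pKa model (the set
#' used by the ExPASy tools) is zero, found by bisection on [0, 14].
#'
#' @param sequence amino-acid string or `construct`.
#' @param tol bisection tolerance in pH units (default 0.01).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 0.01) {
  aa <- check_sequence(seq_of(sequence))
  lo <- 0; hi <- 14
  # termini guarantee charge_at_ph is positive at pH 0, negative at pH 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (charge_at_ph(aa, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' All sequence properties of a construct
#'
#' @param construct a `construct` or plain sequence string.
#' @return list of class `seqprops`: `mw_average`, `mw_monoisotopic`,
#'   `eps280_reduced`, `eps280_cystine` (M^-1 cm^-1), `pI`.
#' @export
sequence_properties <- function(construct) {
  s <- seq_of(construct)
  structure(list(
    name = if (inherits(construct, "construct")) construct$name else NA_character_,
    mw_average = molecular_weight(s, "average"),
    mw_monoisotopic = molecular_weight(s, "monoisotopic"),
    eps280_reduced = extinction_coefficient(s, cystine = FALSE),
    eps280_cystine = extinction_coefficient(s, cystine = TRUE),
    pI = isoelectric_point(s)), class = "seqprops")
}

#' @export
print.seqprops <- function(x, ...) {
  cat(sprintf(paste0(
    "Sequence properties%s:\n",
    "  MW (average)       %10.2f Da\n",
    "  MW (monoisotopic)  %10.5f Da\n",
    "  eps280 reduced     %7d M-1 cm-1\n",
    "  eps280 cystine     %7d M-1 cm-1\n",
    "  pI                 %7.2f\n"),
    if (is.na(x$name)) "" else paste0(" of ", x$name),
    x$mw_average, x$mw_monoisotopic, x$eps280_reduced, x$eps280_cystine, x$pI))
  invisible(x)
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K and R except when the next residue is proline,
#' and enumerates all peptides with up to `max_missed` internal missed
#' cleavage sites.
#'
#' @param sequence amino-acid string or `construct`.
#' @param max_missed maximum internal missed cleavages (default 0).
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages` (positions in the parent sequence).
#' @export
tryptic_peptides <- function(sequence, max_missed = 0L) {
  s <- seq_of(sequence)
  aa <- check_sequence(s)
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  out <- list()
  nseg <- length(starts)
  for (i in seq_len(nseg)) {
    for (m in 0:min(max_missed, nseg - i)) {
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(s, starts[i], ends[i + m]),
        start = starts[i], end = ends[i + m], missed_cleavages = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Monoisotopic mass of a peptide
#'
#' @param sequence amino-acid string.
#' @param carbamidomethyl logical: add +57.02146 Da per cysteine (fixed
#'   iodoacetamide alkylation; default FALSE).
#' @return mass in Da.
#' @export
peptide_mass <- function(sequence, carbamidomethyl = FALSE) {
  aa <- check_sequence(sequence)
  m <- sum(AA_MONO[aa]) + WATER_MONO
  if (carbamidomethyl) m <- m + CARBAMIDOMETHYL * sum(aa == "C")
  m
}

#' Theoretical mass of a cross-linker-bridged peptide pair
#'
#' The monoisotopic mass of two tryptic peptides joined by a cross-linker
#' bridge: `mono(pepA) + mono(pepB) + bridge`, with carbamidomethylation
#' applied to every cysteine except a cross-linked one. Each peptide must
#' contain exactly one residue compatible with its linker end (a
#' cross-linked lysine is an uncleaved tryptic site, so search digests with
#' missed cleavages allowed).
#'
#' @param pepA,pepB peptide sequences.
#' @param linker linker name as in [builtin_linkers()].
#' @param siteA,siteB the cross-linked residue letter in each peptide
#'   (`"K"` or `"C"`); defaults to the single compatible residue.
#' @param carbamidomethyl logical: fixed Cys modification (default TRUE, the
#'   standard alkylation workflow).
#' @param charges charge states for which to report m/z (default 1:4).
#' @return list of class `xl_pair`: `pepA`, `pepB`, `linker`, `mass_mono`
#'   (Da) and `mz` (named vector, Th).
#' @export
crosslinked_pair_mass <- function(pepA, pepB, linker, siteA = NULL,
                                  siteB = NULL, carbamidomethyl = TRUE,
                                  charges = 1:4) {
  lk <- get_linker(linker)
  site_for <- function(pep, chem, site) {
    aa <- check_sequence(pep)
    want <- if (chem == "amine") "K" else "C"
    if (is.null(site)) site <- want
    if (!chem_compatible(site, chem))
      stop("chemistry mismatch: ", linker, " end is ", chem,
           " but site is ", site, call. = FALSE)
    if (sum(aa == site) != 1L)
      stop("peptide ", pep, " must contain exactly one cross-linkable ",
           site, call. = FALSE)
    site
  }
  # assign linker ends in whichever order matches the stated sites
  if (!is.null(siteA) && !chem_compatible(siteA, lk$chem_a) &&
      chem_compatible(siteA, lk$chem_b)) {
    tmp <- lk$chem_a; lk$chem_a <- lk$chem_b; lk$chem_b <- tmp
  } else if (!is.null(siteB) && !chem_compatible(siteB, lk$chem_b) &&
             chem_compatible(siteB, lk$chem_a)) {
    tmp <- lk$chem_a; lk$chem_a <- lk$chem_b; lk$chem_b <- tmp
  }
  sA <- site_for(pepA, lk$chem_a, siteA)
  sB <- site_for(pepB, lk$chem_b, siteB)
  mod_mass <- function(pep, site) {
    aa <- check_sequence(pep)
    ncys <- sum(aa == "C") - (site == "C")  # linked Cys is not alkylated
    peptide_mass(pep) + if (carbamidomethyl) CARBAMIDOMETHYL * ncys else 0
  }
  mass <- mod_mass(pepA, sA) + mod_mass(pepB, sB) + lk$bridge_mass_mono
  mz <- (mass + charges * PROTON_MASS) / charges
  structure(list(pepA = pepA, pepB = pepB, linker = linker,
                 mass_mono = mass, mz = setNames(mz, charges)),
            class = "xl_pair")
}

#' @export
print.xl_pair <- function(x, ...) {
  cat(sprintf("%s =[%s]= %s  mass %0.3f Da\n", x$pepA, x$linker, x$pepB,
              x$mass_mono))
  invisible(x)
}

#' Convert a nanogram amount of a construct to picomoles
#'
#' `mass_ng / MW_average * 1000`.
#'
#' @param mass_ng mass in nanograms.
#' @param construct a `construct` or sequence, or a numeric average MW (Da).
#' @return amount in pmol.
#' @export
ng_to_pmol <- function(mass_ng, construct) {
  stopifnot(all(mass_ng >= 0))
  mw <- if (is.numeric(construct)) construct
        else molecular_weight(construct, "average")
  mass_ng / mw * 1000
}

#' Read construct sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named list of `construct` objects.
#' @export
read_fasta_constructs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    name <- sub("^>\\s*", "", strsplit(lines[hdr[i]], "\\s+")[[1L]][1L])
    name <- sub(">", "", name, fixed = TRUE)
    seqs <- toupper(gsub("\\s", "", paste(lines[from:to], collapse = "")))
    out[[name]] <- protein_construct(name, seqs)
  }
  out
}

# Sequences the source study prints verbatim and the package uses in its
# documented examples: the N-terminal purification tag of the DID construct
# and the DAD peptide used in NMR competition.
#' Printed reference sequences
#'
#' Small sequences printed in the study this package models: the His-tag of
#' the DID expression construct and the synthetic DAD peptide. The
#' UniProt-derived DID/MFN2 construct sequences themselves are not
#' redistributed; fetch them from UniProt (O60610 residues 142-380 for DID,
#' O95140 residues 20-400 plus 706-757 for the MFN2 cytosolic fragment) and
#' load with [read_fasta_constructs()].
#'
#' @return named character vector of sequences.
#' @export
reference_sequences <- function() {
  c(did_tag = "MGSSERSHHHHHHSGSE",
    dad_peptide = "DETGVMDSLLEALQSGAAFRRKRGPRQAN")
}

#' Load the UniProt-derived DID/MFN2 construct sequences
#'
#' The DID and MFN2 expression constructs are defined on UniProt entries
#' O60610 and O95140, whose sequences this package does not redistribute.
#' To compare computed construct properties against their published
#' constants, fetch the two entries once and save a FASTA file with records
#' named `DID_domain` (O60610 residues 142-380), `DID_construct` (the same
#' with the tag `MGSSERSHHHHHHSGSE` prepended), `MFN2_construct` (O95140
#' residues 20-400 joined to 706-757), then pass its path here (or place it
#' at `inst/extdata/uniprot_constructs.fasta` before installation).
#'
#' @param path FASTA path; defaults to the bundled location.
#' @return named list of `construct` objects.
#' @export
load_reference_constructs <- function(path = system.file(
  "extdata", "uniprot_constructs.fasta", package = "tetherdock")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("UniProt-derived construct sequences are not available: ",
         "fetch O60610/O95140 from UniProt and provide a FASTA with ",
         "records DID_domain, DID_construct and MFN2_construct ",
         "(see ?load_reference_constructs)", call. = FALSE)
  cons <- read_fasta_constructs(path)
  need <- c("DID_domain", "DID_construct", "MFN2_construct")
  miss <- setdiff(need, names(cons))
  if (length(miss))
    stop("construct FASTA is missing records: ",
         paste(miss, collapse = ", "), call. = FALSE)
  cons
}
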