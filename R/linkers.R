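# Monoisotopic and average atomic masses (IUPAC standard values) used by
# both the linker table and the peptide mass calculators.
ATOMIC_MONO <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)
ATOMIC_AVG  <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
PROTON_MASS <- 1.007276

# Mass of an elemental formula like "C5H4O2" under a named mass table.
formula_mass <- function(formula, masses) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  total <- 0
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(masses)) stop("unknown element: ", el, call. = FALSE)
    total <- total + masses[[el]] * n
  }
  total
}

#' Built-in cross-linker chemistry table
#'
#' The seven bifunctional reagents used to restrain the DID-DD/MFN2 complex:
#' four homobifunctional amine-to-amine NHS esters (DSG, BS3, BS(PEG)5,
#' BS(PEG)9) and three heterobifunctional amine-to-sulfhydryl
#' NHS-ester/maleimide reagents (KMUS, SMCC, SMPB). The spacer arm length is
#' the maximal through-linker distance between the two reactive atoms and is
#' used as the upper distance bound of derived restraints.
#'
#' Bridge compositions are the mass added to the sum of the two linked
#' peptides: for NHS-ester aminolysis each coupling releases one
#' N-hydroxysuccinimide, so a homobifunctional bridge is the parent diacid
#' minus two waters; maleimide/thiol Michael addition conserves atoms, so a
#' heterobifunctional bridge is the maleimido acid minus one water.
#'
#' @return data.frame keyed by `name` with columns `chem_a`, `chem_b`
#'   (end chemistries), `spacer` (Angstroms), `bridge_formula`,
#'   `bridge_mass_mono` and `bridge_mass_avg` (Da).
#' @export
builtin_linkers <- function() {
  tab <- data.frame(
    name = c("DSG", "BS3", "BS(PEG)5", "BS(PEG)9", "KMUS", "SMCC", "SMPB"),
    chem_a = c("amine", "amine", "amine", "amine", "amine", "amine", "amine"),
    chem_b = c("amine", "amine", "amine", "amine",
               "sulfhydryl", "sulfhydryl", "sulfhydryl"),
    spacer = c(7.7, 11.4, 21.7, 35.8, 16.3, 8.3, 11.6),
    bridge_formula = c("C5H4O2", "C8H10O2", "C14H22O7", "C22H38O11",
                       "C15H19N1O3", "C12H13N1O3", "C14H11N1O3"),
    stringsAsFactors = FALSE
  )
  tab$bridge_mass_mono <- vapply(tab$bridge_formula, formula_mass, 0,
                                 masses = ATOMIC_MONO)
  tab$bridge_mass_avg <- vapply(tab$bridge_formula, formula_mass, 0,
                                masses = ATOMIC_AVG)
  rownames(tab) <- tab$name
  tab
}

#' Look up one cross-linker by name
#'
#' @param name linker name as in [builtin_linkers()].
#' @return single-row data.frame of linker properties.
#' @export
get_linker <- function(name) {
  tab <- builtin_linkers()
  if (!name %in% tab$name) stop("unknown linker: ", name, call. = FALSE)
  tab[tab$name == name, , drop = FALSE]
}
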