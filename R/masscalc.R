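# Monoisotopic masses (Da) of the elements handled by the formula parser.
ELEMENT_MONOISOTOPIC <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                          O = 15.9949146221, S = 31.97207069, P = 30.97376151)

#' Physical constants used in mass arithmetic
#'
#' `proton` is the mass added on protonation of small molecules
#' (\[M+H\]+); `hydrogen_atom` is the per-charge mass subtracted when
#' deconvoluting multiply charged peptide ions (the convention that
#' reproduces molecular weights as printed by common instrument software);
#' `isotope_spacing` is the 13C-12C mass difference that sets the spacing
#' of isotope clusters.
#'
#' @format named numeric vector (Da).
#' @export
MASS_CONSTANTS <- c(proton = 1.007276, hydrogen_atom = 1.00794,
                    isotope_spacing = 1.003355, water = 18.0105646859)

#' Monoisotopic mass of an elemental formula
#'
#' Parses formulas over C, H, N, O, S, P (e.g. `"C8H11NO"` for tyramine)
#' and sums monoisotopic isotope masses. The empty formula has mass 0.
#'
#' @param formula character formula string.
#' @return mass in Da.
#' @examples
#' formula_monoisotopic("C8H11NO")  # tyramine, 137.084
#' @export
formula_monoisotopic <- function(formula) {
  if (is.na(formula) || formula == "") return(0)
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(tokens) || nchar(paste(tokens, collapse = "")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  mass <- 0
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    cnt <- gsub("[^0-9]", "", tok)
    cnt <- if (cnt == "") 1L else as.integer(cnt)
    if (!el %in% names(ELEMENT_MONOISOTOPIC))
      stop("unknown element: ", el)
    mass <- mass + ELEMENT_MONOISOTOPIC[[el]] * cnt
  }
  mass
}

#' Protonated monoisotopic m/z of a formula
#'
#' \[M+H\]+ for a neutral molecule: monoisotopic mass plus the proton mass.
#'
#' @param formula character formula string.
#' @param m_proton proton mass (Da).
#' @return m/z in Da (charge 1).
#' @examples
#' protonated_mz("C8H11NO")  # 138.0913
#' @export
protonated_mz <- function(formula, m_proton = MASS_CONSTANTS[["proton"]]) {
  formula_monoisotopic(formula) + m_proton
}

#' Protonated m/z of a dehydration (or other loss) conjugate
#'
#' Phenylpropanoid amides such as coumaroyl- and feruloyl-tyramine arise by
#' condensation of an acid and an amine with loss of water; their \[M+H\]+
#' is `mass(A) + mass(B) - mass(loss) + proton`.
#'
#' @param formulaA,formulaB elemental formulas of the two moieties.
#' @param loss formula of the neutral lost on conjugation (default `"H2O"`;
#'   `""` for none).
#' @param m_proton proton mass (Da).
#' @return m/z in Da.
#' @examples
#' conjugate_mz("C9H8O3", "C8H11NO")   # coumaroyl-tyramine, 284.13
#' conjugate_mz("C10H10O4", "C8H11NO") # feruloyl-tyramine, 314.14
#' @export
conjugate_mz <- function(formulaA, formulaB, loss = "H2O",
                         m_proton = MASS_CONSTANTS[["proton"]]) {
  m <- formula_monoisotopic(formulaA) + formula_monoisotopic(formulaB) -
    formula_monoisotopic(loss)
  if (m <= 0) stop("loss mass exceeds the conjugate mass")
  m + m_proton
}

# Monoisotopic residue masses of the 20 standard amino acids (Da).
AA_RESIDUE_MONOISOTOPIC <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water (the terminal H and OH).
#'
#' @param sequence one-letter amino-acid string.
#' @return mass in Da.
#' @examples
#' peptide_monoisotopic("PAASYQQHIIGGALF")  # 1571.8096
#' @export
peptide_monoisotopic <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty peptide sequence")
  aas <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aas, names(AA_RESIDUE_MONOISOTOPIC))
  if (length(unknown)) stop("unknown amino acid letter(s): ",
                            paste(unique(unknown), collapse = ", "))
  sum(AA_RESIDUE_MONOISOTOPIC[aas]) + MASS_CONSTANTS[["water"]]
}

#' Neutral mass from a multiply charged ion
#'
#' `M = z * (m/z - m_h)`: each charge carries one hydrogen whose mass is
#' removed per charge.
#'
#' @param mz observed monoisotopic m/z.
#' @param z charge state, >= 1.
#' @param m_h per-charge hydrogen mass (Da).
#' @return neutral mass in Da.
#' @examples
#' neutral_mass(786.910, 2)  # 1571.804
#' neutral_mass(524.943, 3)  # 1571.805
#' @export
neutral_mass <- function(mz, z, m_h = MASS_CONSTANTS[["hydrogen_atom"]]) {
  if (z < 1) stop("charge must be >= 1")
  if (any(mz <= m_h)) stop("m/z must exceed the per-charge hydrogen mass")
  z * (mz - m_h)
}

#' Infer charge state from isotope-cluster spacing
#'
#' Member peaks of an isotope cluster are spaced by ~1.003355/z Da (the
#' 13C-12C difference divided by the charge). The charge is the rounded
#' reciprocal of the mean observed spacing; clusters whose individual
#' spacings deviate from the implied ideal by more than the tolerance are
#' rejected as irregular.
#'
#' @param mzs member m/z values (>= 2 peaks; any order).
#' @param tol_ppm spacing tolerance, expressed in ppm of the cluster m/z
#'   and applied as `2 * tol_ppm * 1e-6 * mean(mzs)` Da per spacing (each
#'   spacing involves two jittered peak positions).
#' @return An object of class `isotope_cluster`: list with `mzs` (sorted),
#'   `z`, `monoisotopic_mz` (lowest member), `mean_spacing`.
#' @examples
#' detect_charge(c(786.910, 787.412, 787.913))  # z = 2
#' @export
detect_charge <- function(mzs, tol_ppm = 25) {
  if (length(mzs) < 2L) stop("need at least 2 cluster peaks")
  mzs <- sort(as.numeric(mzs))
  sp <- diff(mzs)
  mean_sp <- mean(sp)
  z <- round(MASS_CONSTANTS[["isotope_spacing"]] / mean_sp)
  if (is.na(z) || z < 1)
    stop("spacing ", signif(mean_sp, 4), " Da implies no valid charge state")
  ideal <- MASS_CONSTANTS[["isotope_spacing"]] / z
  tol_da <- 2 * tol_ppm * 1e-6 * mean(mzs)
  if (any(abs(sp - ideal) > tol_da))
    stop(sprintf("irregular isotope spacing (max deviation %.4g Da > tol %.4g Da)",
                 max(abs(sp - ideal)), tol_da))
  structure(list(mzs = mzs, z = as.integer(z), monoisotopic_mz = mzs[1L],
                 mean_spacing = mean_sp),
            class = "isotope_cluster")
}

#' @export
print.isotope_cluster <- function(x, ...) {
  cat(sprintf("isotope_cluster: z = %d, monoisotopic m/z %.4f, %d peaks\n",
              x$z, x$monoisotopic_mz, length(x$mzs)))
  invisible(x)
}

#' Annotation record for a feature or spectrum
#'
#' @param id feature/spectrum identifier.
#' @param identity proposed identity.
#' @param confidence identification confidence level, integer 1 (confirmed
#'   by standard) to 4 (unknown).
#' @param evidence free-text evidence notes.
#' @return data.frame row of class `annotation_record`.
#' @export
annotation_record <- function(id, identity, confidence, evidence = "") {
  if (!confidence %in% 1:4) stop("confidence level must be 1, 2, 3 or 4")
  structure(data.frame(id = id, identity = identity,
                       confidence = as.integer(confidence),
                       evidence = evidence, stringsAsFactors = FALSE),
            class = c("annotation_record", "data.frame"))
}
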