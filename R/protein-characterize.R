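## ORF translation, protein molecular mass, residue differences, gel
## filtration calibration (Kav vs log10 mass), apparent native mass and
## oligomer order.

# average masses of amino acid residues (Da; free amino acid minus water)
AA_MASS_AVERAGE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_AVERAGE <- 18.01528
WATER_MONO <- 18.010565

#' Translate an open reading frame
#'
#' Standard-code translation of a complete ORF. The length must be a
#' multiple of 3; an internal stop codon is an error (reported with its
#' codon position); a single terminal stop codon is consumed and not
#' represented in the protein, so a stop-terminated ORF of `3(L+1)` bases
#' encodes `L` residues (2370 bp encodes 789 amino acids).
#'
#' @param dna DNA string (A/C/G/T).
#' @param require_start require the first codon to be ATG (default `TRUE`).
#' @return object of class `orf_translation`: list with `dna_length`,
#'   `protein`, `protein_length`.
#' @examples
#' translate_orf("ATGTAA")$protein # "M"
#' @export
translate_orf <- function(dna, require_start = TRUE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0 || n %% 3 != 0) {
    stop_btchar("ORF length ", n, " is not a positive multiple of 3",
                class = "btchar_frame_error")
  }
  chars <- strsplit(dna, "")[[1]]
  bad <- setdiff(chars, c("A", "C", "G", "T"))
  if (length(bad)) {
    stop_btchar("non-ACGT character(s): ", paste(unique(bad), collapse = ", "),
                class = "btchar_invalid_base")
  }
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  if (require_start && codons[1] != "ATG") {
    stop_btchar("ORF does not start with ATG", class = "btchar_no_start")
  }
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aas == "*")
  n_codon <- length(codons)
  if (length(stops) && any(stops < n_codon)) {
    stop_btchar("internal stop codon at codon ", stops[stops < n_codon][1],
                class = "btchar_premature_stop")
  }
  if (length(stops) && stops[length(stops)] == n_codon) {
    aas <- aas[-n_codon]
  }
  structure(list(dna_length = n, protein = paste(aas, collapse = ""),
                 protein_length = length(aas)),
            class = "orf_translation")
}

#' @export
print.orf_translation <- function(x, ...) {
  cat("ORF translation: ", x$dna_length, " bp -> ", x$protein_length,
      " residues\n", sep = "")
  invisible(x)
}

#' Molecular mass of a protein
#'
#' Sum of residue masses plus one water, using the standard average (default)
#' or monoisotopic mass tables.
#'
#' @param protein residue string over the 20 standard amino acids (empty
#'   string returns the mass of water).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @examples
#' molecular_mass("G") # 75.07 (glycine)
#' @export
molecular_mass <- function(protein, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  tab <- if (mode == "average") AA_MASS_AVERAGE else AA_MASS_MONO
  water <- if (mode == "average") WATER_AVERAGE else WATER_MONO
  if (!nzchar(protein)) return(water)
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(chars, names(tab))
  if (length(bad)) {
    stop_btchar("unknown residue(s): ", paste(unique(bad), collapse = ", "),
                class = "btchar_invalid_residue")
  }
  sum(tab[chars]) + water
}

#' Positionwise residue differences between two equal-length proteins
#'
#' No alignment is performed: sequences must be the same length and are
#' compared position by position (the comparison the Vip3Aa65 vs Vip3Aa16
#' difference table is built from).
#'
#' @param a,b residue strings of equal length.
#' @return data.frame with columns `position` (1-based), `residue_a`,
#'   `residue_b`; zero rows when identical.
#' @export
residue_differences <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop_btchar("sequences differ in length (", nchar(a), " vs ", nchar(b),
                "); no alignment is performed", class = "btchar_length_mismatch")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  data.frame(position = pos, residue_a = ca[pos], residue_b = cb[pos],
             stringsAsFactors = FALSE)
}

#' Fit a size-exclusion calibration curve
#'
#' Least-squares line of the partition coefficient
#' `Kav = (Ve - V0) / (Vc - V0)` on `log10(mass)` over the calibration
#' standards. The slope is negative on a working column (larger proteins
#' elute earlier).
#'
#' @param standards data.frame with columns `mass_kda` and `ve_ml`
#'   (>= 2 distinct masses).
#' @param V0 void volume (ml).
#' @param Vc geometric column volume (ml); `V0 < Vc`.
#' @return object of class `calibration_curve`: `slope`, `intercept`,
#'   `V0`, `Vc`, `r_squared`.
#' @export
fit_calibration <- function(standards, V0, Vc) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "ve_ml") %in% names(standards)))
  if (V0 >= Vc) stop_btchar("V0 must be < Vc", class = "btchar_bad_column")
  if (length(unique(standards$mass_kda)) < 2) {
    stop_btchar("need >= 2 standards with distinct masses",
                class = "btchar_no_input")
  }
  if (any(standards$mass_kda <= 0)) {
    stop_btchar("standard masses must be positive", class = "btchar_bad_mass")
  }
  if (any(standards$ve_ml < V0 | standards$ve_ml > Vc)) {
    stop_btchar("elution volume outside [V0, Vc]", class = "btchar_bad_volume")
  }
  kav <- (standards$ve_ml - V0) / (Vc - V0)
  logm <- log10(standards$mass_kda)
  fit <- stats::lm(kav ~ logm)
  ss_tot <- sum((kav - mean(kav))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 V0 = V0, Vc = Vc, r_squared = r2),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("SEC calibration: Kav = %.4f * log10(kDa) + %.4f (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  column: V0 = %.2f ml, Vc = %.2f ml\n", x$V0, x$Vc))
  invisible(x)
}

#' Apparent molecular mass from an elution volume
#'
#' Inverts the calibration line: `mass = 10^((Kav - intercept) / slope)`.
#'
#' @param curve a `calibration_curve`.
#' @param Ve elution volume (ml), inside `[V0, Vc]`.
#' @return apparent mass in kDa.
#' @export
apparent_mw <- function(curve, Ve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (Ve < curve$V0 || Ve > curve$Vc) {
    stop_btchar("Ve = ", Ve, " outside column range [", curve$V0, ", ",
                curve$Vc, "]", class = "btchar_bad_volume")
  }
  kav <- (Ve - curve$V0) / (curve$Vc - curve$V0)
  10^((kav - curve$intercept) / curve$slope)
}

#' Oligomer order from apparent and monomer mass
#'
#' Nearest integer to `apparent / monomer`, with a floor of 1: a 346 kDa
#' native species of an 88.5 kDa monomer is a tetramer.
#'
#' @param apparent_mass apparent native mass (kDa).
#' @param monomer_mass monomer mass (kDa).
#' @return integer oligomer order (>= 1).
#' @examples
#' oligomer_order(346, 88.5) # 4
#' oligomer_order(80.3, 88.5) # 1
#' @export
oligomer_order <- function(apparent_mass, monomer_mass) {
  stopifnot(apparent_mass > 0, monomer_mass > 0)
  max(1L, as.integer(round_half_up(apparent_mass / monomer_mass)))
}

#' Full gel-filtration interpretation of one elution peak
#'
#' @param curve a `calibration_curve`.
#' @param Ve elution volume (ml).
#' @param monomer_mass monomer mass (kDa).
#' @return list with `Ve`, `Kav`, `apparent_mass`, `monomer_mass`,
#'   `oligomer_order`.
#' @export
gel_filtration_result <- function(curve, Ve, monomer_mass) {
  mass <- apparent_mw(curve, Ve)
  list(Ve = Ve,
       Kav = (Ve - curve$V0) / (curve$Vc - curve$V0),
       apparent_mass = mass,
       monomer_mass = monomer_mass,
       oligomer_order = oligomer_order(mass, monomer_mass))
}
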