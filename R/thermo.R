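#' Nearest-neighbor parameter table for RNA-DNA hybrids
#'
#' Loads the dinucleotide stacking parameters (Sugimoto et al. 1995) used to
#' predict the melting temperature of an RNA-DNA heteroduplex. The table is
#' keyed by the RNA-strand dinucleotide read 5'->3'; the antisense DNA oligo
#' is the reverse complement and never indexes the table itself. It ships as
#' a plain-text resource so it can be audited or swapped for an updated
#' parameter set without code changes.
#'
#' @param path Path to a tab-separated file with columns `dinucleotide`,
#'   `deltaH_kcal`, `deltaS_cal` (lines starting with `#` are comments).
#'   Defaults to the packaged Sugimoto et al. 1995 table.
#' @return An object of class `nn_table`: a list with named numeric vectors
#'   `deltaH` (kcal/mol) and `deltaS` (cal/(K*mol)), one entry per RNA
#'   dinucleotide (16 keys over ACGU).
#' @examples
#' tab <- nn_table()
#' tab$deltaH[["AU"]]
#' @export
nn_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_rna_dna_sugimoto1995.tsv",
                        package = "oligotiler", mustWork = TRUE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("dinucleotide", "deltaH_kcal", "deltaS_cal")
  if (!all(need %in% names(df))) {
    stop("nn_table file must have columns: ", paste(need, collapse = ", "))
  }
  keys <- toupper(df$dinucleotide)
  expected <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0))
  if (length(keys) != 16L || anyDuplicated(keys) ||
      !setequal(keys, expected)) {
    stop("nn_table must contain exactly the 16 RNA dinucleotides over ACGU")
  }
  dH <- stats::setNames(as.numeric(df$deltaH_kcal), keys)
  dS <- stats::setNames(as.numeric(df$deltaS_cal), keys)
  if (any(!is.finite(dH)) || any(!is.finite(dS))) {
    stop("nn_table contains non-finite values")
  }
  if (any(dH >= 0) || any(dS >= 0)) {
    stop("all nn_table deltaH and deltaS entries must be negative")
  }
  structure(list(deltaH = dH, deltaS = dS), class = "nn_table")
}

#' Thermodynamic configuration for melting-temperature prediction
#'
#' Bundles every constant of the Tm formula. The formula is evaluated exactly
#' as
#' \deqn{T_m = \frac{\Delta H - \Delta H_{init}}
#'   {\Delta S + R \ln(1/[\mathrm{oligo}]) + 16.6 \log_{10}([\mathrm{Na}^+])}
#'   - 273.15}
#' with \eqn{\Delta H} in cal/mol, \eqn{\Delta S} in cal/(K mol), and the salt
#' term inside the denominator. No alternative ("corrected") formula is
#' substituted.
#'
#' The default oligo concentration is 5e-2 mol/L, the literal reading of a
#' 50 mM design concentration; a 50 nM reading (`oligo_conc = 5e-8`) is a
#' supported alternative. Ratio-based properties (such as the concentration
#' sensitivity bound) are invariant to this choice; absolute Tm values are
#' not, so the value in force is carried in the config and echoed by the CLI.
#'
#' @param nn An [nn_table()].
#' @param oligo_conc Oligo strand concentration, mol/L (> 0). Default 5e-2.
#' @param na_conc Sodium concentration, mol/L (> 0). Default 0.2.
#' @param helix_init_energy Helix initiation enthalpy, kcal/mol. Default -3.1,
#'   applied literally: the numerator is deltaH - (-3.1) kcal/mol.
#' @param gas_constant Gas constant R, cal/(K*mol); fixed at 1.987.
#' @return An object of class `thermo_config`.
#' @examples
#' cfg <- thermo_config()
#' melting_temperature(strrep("GC", 20), cfg)
#' @export
thermo_config <- function(nn = nn_table(), oligo_conc = 5e-2, na_conc = 0.2,
                          helix_init_energy = -3.1, gas_constant = 1.987) {
  stopifnot(inherits(nn, "nn_table"))
  if (!is.numeric(oligo_conc) || length(oligo_conc) != 1L || oligo_conc <= 0) {
    stop("oligo_conc must be a single positive number (mol/L)")
  }
  if (!is.numeric(na_conc) || length(na_conc) != 1L || na_conc <= 0) {
    stop("na_conc must be a single positive number (mol/L)")
  }
  if (!identical(gas_constant, 1.987)) {
    stop("gas_constant is fixed at 1.987 cal/(K*mol)")
  }
  structure(list(nn = nn, oligo_conc = oligo_conc, na_conc = na_conc,
                 helix_init_energy = helix_init_energy,
                 gas_constant = gas_constant),
            class = "thermo_config")
}

# Uppercase, DNA->RNA (T->U), and validate alphabet; names the first
# offending position in the error message.
normalize_rna <- function(seq, allow_n = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  ok <- if (allow_n) c("A", "C", "G", "U", "N") else c("A", "C", "G", "U")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% ok)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (alphabet ACGU/T%s)",
                 ch[bad[1L]], bad[1L], if (allow_n) "/N" else ""))
  }
  s
}

#' Sum nearest-neighbor stack enthalpies and entropies
#'
#' Sums the tabulated deltaH and deltaS over the L-1 adjacent dinucleotide
#' stacks of a target RNA subsequence (read along the RNA strand 5'->3').
#'
#' @param target_subseq RNA string, length >= 2, alphabet ACGU (T is accepted
#'   and mapped to U).
#' @param table An [nn_table()].
#' @return Named numeric vector `c(deltaH = , deltaS = )` in kcal/mol and
#'   cal/(K*mol).
#' @examples
#' stack_sums("AAAA", nn_table())  # 3 * the AA entry
#' @export
stack_sums <- function(target_subseq, table = nn_table()) {
  stopifnot(inherits(table, "nn_table"))
  s <- normalize_rna(target_subseq)
  n <- nchar(s)
  if (n < 2L) stop("target_subseq must have length >= 2")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  stacks <- paste0(ch[-n], ch[-1L])
  c(deltaH = sum(table$deltaH[stacks]), deltaS = sum(table$deltaS[stacks]))
}

#' Predict the melting temperature of an RNA-DNA hybrid
#'
#' Computes Tm (degrees C) for the duplex formed by a target RNA subsequence
#' and its exactly complementary antisense DNA oligo, by nearest-neighbor
#' stack summation and the formula documented under [thermo_config()].
#' deltaH is converted from kcal/mol to cal/mol before the division.
#'
#' A pure, deterministic function of (sequence, config). Vectorized over
#' `target_subseq`.
#'
#' @param target_subseq Character vector of RNA strings (ACGU; T mapped to U),
#'   each of length >= 2.
#' @param cfg A [thermo_config()].
#' @return Numeric vector of melting temperatures in degrees C.
#' @examples
#' melting_temperature(strrep("A", 40), thermo_config())
#' @export
melting_temperature <- function(target_subseq, cfg = thermo_config()) {
  stopifnot(inherits(cfg, "thermo_config"))
  salt_term <- cfg$gas_constant * log(1 / cfg$oligo_conc) +
    16.6 * log10(cfg$na_conc)
  vapply(target_subseq, function(s) {
    ss <- stack_sums(s, cfg$nn)
    num <- ss[["deltaH"]] * 1000 - cfg$helix_init_energy * 1000
    den <- ss[["deltaS"]] + salt_term
    if (abs(den) < 1e-9) {
      stop("degenerate Tm denominator: non-physical thermodynamic parameters")
    }
    num / den - 273.15
  }, numeric(1L), USE.NAMES = FALSE)
}

# Tm of a possibly IUPAC-degenerate target subsequence: the minimum over all
# unambiguous expansions (conservative hybridization guarantee).
wildcard_tm <- function(seq, cfg) {
  min(melting_temperature(expand_wildcards(seq), cfg))
}

# Distance of a Tm from the ideal range [tm_min, tm_max]; 0 inside.
tm_range_distance <- function(tm, tm_min, tm_max) {
  ifelse(tm < tm_min, tm_min - tm, ifelse(tm > tm_max, tm - tm_max, 0))
}
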