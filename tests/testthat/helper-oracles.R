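# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: the NN table is a hand-entered copy, the Tm
# formula is a one-line evaluation, and the interval/complementarity checks
# use their own string arithmetic.

# Hand-entered copy of the published RNA-DNA hybrid stacking parameters,
# keyed by RNA dinucleotide (kcal/mol, cal/(K*mol)).
ORACLE_NN <- data.frame(
  din = c("AA", "AC", "AG", "AU", "CA", "CC", "CG", "CU",
          "GA", "GC", "GG", "GU", "UA", "UC", "UG", "UU"),
  dH = c(-7.8, -5.9, -9.1, -8.3, -9.0, -9.3, -16.3, -7.0,
         -5.5, -8.0, -12.8, -7.8, -7.8, -8.6, -10.4, -11.5),
  dS = c(-21.9, -12.3, -23.5, -23.9, -26.1, -23.2, -47.1, -19.7,
         -13.5, -17.1, -31.9, -21.6, -23.2, -22.9, -28.4, -36.4),
  stringsAsFactors = FALSE)

oracle_stack_sums <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(ch) - 1L)) {
    row <- ORACLE_NN[ORACLE_NN$din == paste0(ch[i], ch[i + 1L]), ]
    dH <- dH + row$dH
    dS <- dS + row$dS
  }
  c(dH = dH, dS = dS)
}

oracle_tm <- function(seq, oligo_conc = 5e-2, na_conc = 0.2,
                      init = -3.1) {
  ss <- oracle_stack_sums(seq)
  (ss[["dH"]] * 1000 - init * 1000) /
    (ss[["dS"]] + 1.987 * log(1 / oligo_conc) + 16.6 * log10(na_conc)) -
    273.15
}

# Independent reverse complement (plain ACGU/T only).
oracle_rc_dna <- function(seq) {
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "", fixed = TRUE)[[1L]]
  paste(rev(chartr("ACGT", "TGCA", ch)), collapse = "")
}

# Independent constraint checker for a tiling: interval order/disjointness,
# gap bound, complementarity and base accounting. Returns a character
# vector of violations (empty when the tiling is sound).
check_tiling <- function(result, params) {
  probs <- character()
  ol <- result$oligos
  L <- result$target_length
  flagged <- length(result$flags) > 0
  if (nrow(ol) == 0) {
    if (L > params$max_gap && !flagged) probs <- c(probs, "empty unflagged")
    return(probs)
  }
  if (is.unsorted(ol$start, strictly = TRUE)) {
    probs <- c(probs, "starts not strictly sorted")
  }
  bounds <- c(0L, as.vector(rbind(ol$start, ol$end)), L)
  for (i in seq_len(nrow(ol))) {
    s <- ol$start[i]; e <- ol$end[i]
    if (e - s < params$len_min || e - s > params$len_max) {
      probs <- c(probs, sprintf("oligo %d length %d out of range", i, e - s))
    }
    if (i > 1 && s < ol$end[i - 1]) {
      probs <- c(probs, sprintf("oligo %d overlaps previous", i))
    }
    fp <- substr(result$target$seq, s + 1, e)
    if (ol$n_expansions[i] == 1 &&
        oracle_rc_dna(fp) != chartr("U", "T", ol$antisense_seq[i])) {
      probs <- c(probs, sprintf("oligo %d not antisense of footprint", i))
    }
  }
  gaps <- c(ol$start[1], if (nrow(ol) > 1) ol$start[-1] - ol$end[-nrow(ol)],
            L - ol$end[nrow(ol)])
  if (any(gaps < 0)) probs <- c(probs, "negative gap")
  if (any(gaps > params$max_gap) && !flagged) {
    probs <- c(probs, "gap exceeds max_gap without flag")
  }
  if (sum(ol$end - ol$start) + sum(gaps) != L) {
    probs <- c(probs, "bases + gaps != target length")
  }
  probs
}

min_flank_gaps <- function(result) {
  ol <- result$oligos
  n <- nrow(ol)
  if (n == 0) return(numeric())
  lo <- c(0L, ol$end[-n])
  hi <- c(ol$start[-1L], result$target_length)
  pmin(ol$start - lo, hi - ol$end)
}

# Simulated RNaseH digestion: cut coordinates on the target, surviving
# piece lengths measured from coordinates (independent of the gap+halves
# arithmetic). Partial digestion assumes one cleavage within the central
# nucleotide of each oligo footprint, taking the pessimistic cut side for
# each flank.
simulate_fragments <- function(result, mode) {
  ol <- result$oligos
  L <- result$target_length
  n <- nrow(ol)
  if (n == 0) return(L)
  if (mode == "complete") {
    cuts_lo <- c(0L, ol$end)
    cuts_hi <- c(ol$start, L)
    return(cuts_hi - cuts_lo)
  }
  len <- ol$end - ol$start
  cut_up <- ol$start + floor(len / 2)    # leaves ceil(len/2) downstream
  cut_down <- ol$start + ceiling(len / 2)  # leaves ceil(len/2) upstream
  c(cut_down[1] - 0L,
    if (n > 1) cut_down[-1] - cut_up[-n],
    L - cut_up[n])
}

# Mock design with a given oligo count for pricing-path tests.
mock_design <- function(n_oligos, target_len = n_oligos * 60L) {
  seq <- strrep("A", target_len)
  starts <- as.integer(seq(0, target_len - 40L, length.out = n_oligos))
  ol <- data.frame(
    id = sprintf("t_%d_39", starts + 1L), target_id = "t",
    start = starts, end = starts + 39L,
    antisense_seq = strrep("T", 39L), tm = 75, tm_in_range = TRUE,
    oligo_class = "individual", n_expansions = 1L,
    stringsAsFactors = FALSE)
  oligotiler:::make_tiling_result(target_seq("t", seq), ol, character())
}
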