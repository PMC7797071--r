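# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Summarize a design against the end-to-end baseline
#'
#' Counts distinct oligos and tiled bases, prices the pool, and compares it
#' with the traditional end-to-end fixed-length tiling of the same targets
#' ([tile_end_to_end()]). Costs are kept at full precision; the print method
#' rounds to whole currency units.
#'
#' @param design A `tiling_result` or `shared_design`.
#' @param unit_price Price per designed oligo (short oligos typically get
#'   value pricing).
#' @param baseline_unit_price Price per baseline oligo.
#' @param baseline_len Baseline oligo length, nt (default 50).
#' @return An object of class `design_summary` with fields `n_oligos`,
#'   `bases_tiled`, `total_target_bases`, `fraction_tiled`, `cost`,
#'   `baseline_n_oligos`, `baseline_bases`, `baseline_cost` and
#'   `percent_cost_reduction` (`100 * (1 - cost / baseline_cost)`).
#' @examples
#' t <- make_synthetic_target(500, gc = 0.5, seed = 2)
#' summarize_design(design_oligos(t), unit_price = 4.64,
#'                  baseline_unit_price = 19)
#' @export
summarize_design <- function(design, unit_price = 4.64,
                             baseline_unit_price = 19, baseline_len = 50L) {
  stopifnot(unit_price >= 0, baseline_unit_price >= 0)
  tilings <- design_tilings(design)
  ids <- unlist(lapply(tilings, function(tr) tr$oligos$id))
  n <- length(unique(ids))
  bases <- sum(vapply(tilings, `[[`, numeric(1L), "bases_tiled"))
  total <- sum(vapply(tilings, `[[`, numeric(1L), "target_length"))
  base <- tile_end_to_end(vapply(tilings, `[[`, numeric(1L),
                                 "target_length"), baseline_len)
  cost <- n * unit_price
  bcost <- base$n_oligos * baseline_unit_price
  structure(list(n_oligos = n, bases_tiled = bases,
                 total_target_bases = total,
                 fraction_tiled = if (total > 0) bases / total else 0,
                 cost = cost,
                 baseline_n_oligos = base$n_oligos,
                 baseline_bases = base$bases,
                 baseline_cost = bcost,
                 percent_cost_reduction =
                   if (bcost > 0) 100 * (1 - cost / bcost) else NA_real_),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("<design_summary> %d oligos tiling %d/%d nt (%.1f%%)\n",
              x$n_oligos, x$bases_tiled, x$total_target_bases,
              100 * x$fraction_tiled))
  cat(sprintf("  cost %.0f vs baseline %.0f (%d x %d-mers): %.0f%% reduction\n",
              round(x$cost), round(x$baseline_cost), x$baseline_n_oligos,
              ceiling(x$baseline_bases / max(x$baseline_n_oligos, 1L)),
              round(x$percent_cost_reduction)))
  invisible(x)
}

#' Predict RNaseH digestion fragment lengths
#'
#' Sizes of the target fragments that survive digestion, used to verify
#' that a size-selection cutoff will remove them. With complete digestion
#' every oligo-covered stretch is destroyed and the untiled gaps themselves
#' remain. With partial digestion each flanking oligo is assumed to induce a
#' single cut at the center of its footprint, so an internal gap keeps half
#' of each flanking oligo attached; terminal gaps gain one flank only.
#'
#' @param tiling A `tiling_result`.
#' @param mode `"complete"` or `"partial"`.
#' @return Integer vector of predicted fragment lengths, one per untiled gap
#'   (head, internal gaps, tail).
#' @export
predicted_fragment_lengths <- function(tiling,
                                       mode = c("complete", "partial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tiling, "tiling_result"))
  gaps <- tiling$gaps
  if (mode == "complete") return(as.integer(gaps))
  n <- nrow(tiling$oligos)
  if (n == 0L) return(as.integer(gaps))
  half <- as.integer(ceiling((tiling$oligos$end - tiling$oligos$start) / 2))
  up <- c(0L, half)        # half-oligo upstream of gap i (none for head)
  down <- c(half, 0L)      # half-oligo downstream of gap i (none for tail)
  as.integer(gaps + up + down)
}

#' Molar concentration of an RNA target in a reaction
#'
#' Converts a mass of single-stranded RNA into its molar concentration,
#' e.g. to check that each depletion oligo is in excess of its target.
#'
#' @param mass_ng Mass of the RNA species, ng.
#' @param length_nt Length of the RNA, nt.
#' @param volume_ul Reaction volume, microliters.
#' @param residue_mass_g_per_mol Average mass per nucleotide residue for
#'   single-stranded RNA (default 320.5 g/mol).
#' @return Concentration in nM.
#' @examples
#' target_molarity(530, 4000, 10)  # ~41 nM
#' @export
target_molarity <- function(mass_ng, length_nt, volume_ul,
                            residue_mass_g_per_mol = 320.5) {
  args <- c(mass_ng = mass_ng, length_nt = length_nt,
            volume_ul = volume_ul,
            residue_mass_g_per_mol = residue_mass_g_per_mol)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all arguments must be positive numbers")
  }
  mass_ng * 1e6 / (length_nt * residue_mass_g_per_mol * volume_ul)
}

#' Generate a reproducible synthetic target RNA
#'
#' i.i.d. bases with the requested GC content; a pure function of
#' `(length, gc, seed)`. Stands in for rRNA targets in tests and examples.
#'
#' @param length Target length, nt (>= 1).
#' @param gc Expected GC fraction in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A [target_seq()] with id `synth_<seed>`.
#' @export
make_synthetic_target <- function(length, gc = 0.5, seed = 0L) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "U"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  target_seq(sprintf("synth_%d", as.integer(seed)), seq)
}

#' Generate a divergent target pair as a gap-free alignment
#'
#' Produces two sequences at a requested percent identity by random
#' substitution (no indels), mimicking divergent rRNA variant pairs such as
#' the ~86%-similar maternal and somatic zebrafish nuclear rRNAs. As in
#' real rRNA variant pairs — where divergence concentrates in variable
#' expansion segments while core regions stay identical — substitutions are
#' clustered: the sequence is segmented into alternating conserved and
#' variable blocks and nearly all substitutions fall inside the variable
#' blocks, leaving conserved stretches long enough to host shared oligos.
#' The substitution count is fixed at `round((1 - identity) * length)`, so
#' realized identity is within 1/length of the request. Returned
#' pre-aligned (columns = positions) with column maps.
#'
#' @param length Sequence length, nt.
#' @param identity Target pairwise identity in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param gc Expected GC fraction of the first sequence.
#' @return An [alignment()] with rows `variant_a`, `variant_b`.
#' @examples
#' make_divergent_pair(1000, identity = 0.86, seed = 5)
#' @export
make_divergent_pair <- function(length, identity, seed = 0L, gc = 0.5) {
  stopifnot(length >= 1L, identity >= 0, identity <= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "U")
    a <- sample(bases, length, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    b <- a
    n_sub <- round((1 - identity) * length)
    if (n_sub > 0) {
      # alternating conserved (~60-150 nt) / variable (~20-80 nt) blocks
      variable <- logical(length)
      pos <- 0L
      in_var <- FALSE
      while (pos < length) {
        len <- if (in_var) sample(20:80, 1L) else sample(60:150, 1L)
        hi <- min(length, pos + len)
        if (in_var) variable[(pos + 1L):hi] <- TRUE
        pos <- hi
        in_var <- !in_var
      }
      var_pos <- which(variable)
      n_var <- min(n_sub, length(var_pos))
      sub_pos <- if (n_var > 0) sample(var_pos, n_var) else integer()
      if (n_sub > n_var) {    # spill over when identity is very low
        sub_pos <- c(sub_pos, sample(which(!variable), n_sub - n_var))
      }
      for (p in sub_pos) b[p] <- sample(setdiff(bases, a[p]), 1L)
    }
    alignment(c("variant_a", "variant_b"),
              c(paste(a, collapse = ""), paste(b, collapse = "")))
  })
}

#' Generate random oligo-scale RNA sequences with bounded GC
#'
#' Each sequence draws a length uniformly from `[len_min, len_max]` and a GC
#' fraction uniformly from `[gc_min, gc_max]`; base counts are fixed to the
#' drawn GC (so realized GC is always inside the band) and shuffled.
#' Deterministic for a fixed seed. Used for thermodynamic property checks.
#'
#' @param n Number of sequences.
#' @param len_min,len_max Length range, nt.
#' @param gc_min,gc_max GC-fraction range.
#' @param seed Integer RNG seed.
#' @return Character vector of RNA sequences.
#' @export
random_oligo_set <- function(n, len_min = 39L, len_max = 40L, gc_min = 0.4,
                             gc_max = 0.6, seed = 1L) {
  stopifnot(n >= 1L, len_min <= len_max, gc_min <= gc_max)
  with_seed(seed, vapply(seq_len(n), function(i) {
    L <- sample(seq.int(len_min, len_max), 1L)
    gc <- stats::runif(1L, gc_min, gc_max)
    n_gc <- round(L * gc)
    n_g <- sample.int(n_gc + 1L, 1L) - 1L
    n_a <- sample.int(L - n_gc + 1L, 1L) - 1L
    paste(sample(c(rep("G", n_g), rep("C", n_gc - n_g), rep("A", n_a),
                   rep("U", L - n_gc - n_a))), collapse = "")
  }, character(1L)))
}
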