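#' Tiling constraints
#'
#' The user-tunable constraints of the gapped tiling design. Defaults are the
#' standard depletion-oligo settings: melting temperature between 70 and
#' 80 degrees C, oligo length 39-40 nt, and at most 30 nt left untiled
#' between consecutive oligos (short enough that complete digestion products
#' are removed by a >200 nt size selection). `max_expansion` bounds how many
#' unambiguous oligos an IUPAC wildcard oligo may expand to in shared-pool
#' consensus designs (default 2, i.e. at most one two-fold wildcard).
#'
#' @param tm_min,tm_max Ideal Tm range, degrees C.
#' @param len_min,len_max Oligo length range, nt.
#' @param max_gap Maximum untiled run between oligos (and at either end), nt.
#' @param max_expansion Maximum number of unambiguous sequences a wildcard
#'   oligo may represent.
#' @return An object of class `tiling_params`.
#' @examples
#' tiling_params(max_gap = 20)
#' @export
tiling_params <- function(tm_min = 70, tm_max = 80, len_min = 39L,
                          len_max = 40L, max_gap = 30L, max_expansion = 2L) {
  len_min <- as.integer(len_min); len_max <- as.integer(len_max)
  max_gap <- as.integer(max_gap); max_expansion <- as.integer(max_expansion)
  if (len_min > len_max) stop("len_min must be <= len_max")
  if (len_min < 2L) stop("len_min must be >= 2")
  if (!(tm_min < tm_max)) stop("tm_min must be < tm_max")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (max_expansion < 1L) stop("max_expansion must be >= 1")
  structure(list(tm_min = tm_min, tm_max = tm_max, len_min = len_min,
                 len_max = len_max, max_gap = max_gap,
                 max_expansion = max_expansion),
            class = "tiling_params")
}

# Empty oligo data.frame in the internal (0-based half-open) layout.
empty_oligos <- function() {
  data.frame(id = character(), target_id = character(), start = integer(),
             end = integer(), antisense_seq = character(), tm = numeric(),
             tm_in_range = logical(), oligo_class = character(),
             n_expansions = integer(), stringsAsFactors = FALSE)
}

oligo_name <- function(target_id, start, len, wildcard) {
  paste0(target_id, "_", start + 1L, "_", len, ifelse(wildcard, "_wc", ""))
}

# Build one oligo row from a candidate (start/end/target_subseq/tm/nexp).
oligo_row <- function(target_id, cand, params, oligo_class = "individual") {
  len <- cand$end - cand$start
  data.frame(id = oligo_name(target_id, cand$start, len,
                             cand$n_expansions > 1L),
             target_id = target_id, start = cand$start, end = cand$end,
             antisense_seq = reverse_complement(cand$target_subseq, "DNA"),
             tm = cand$tm, tm_in_range = cand$tm_in_range,
             oligo_class = oligo_class, n_expansions = cand$n_expansions,
             stringsAsFactors = FALSE)
}

#' Enumerate placeable candidate oligos in a start window
#'
#' All oligos whose start lies in `[window_start, window_end]` (0-based),
#' whose length is within the configured range, that fit on the target, and
#' that do not overlap an `N` (plain targets) or a masked column (consensus
#' targets). On a consensus target, candidates spanning wildcard columns are
#' kept only while their expansion count stays within
#' `params$max_expansion`, and their Tm is the minimum over the expansions.
#'
#' @param target A [target_seq()] (or a consensus target from
#'   [build_consensus()]).
#' @param window_start,window_end Inclusive 0-based bounds for the candidate
#'   start coordinate.
#' @param params A [tiling_params()].
#' @param cfg A [thermo_config()].
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `target_subseq`, `tm`, `tm_in_range`, `n_expansions`; zero rows when
#'   the window admits no candidate.
#' @export
enumerate_candidates <- function(target, window_start, window_end, params,
                                 cfg) {
  L <- target$length
  stopifnot(window_start >= 0, window_start <= window_end, window_end <= L)
  ch <- strsplit(target$seq, "", fixed = TRUE)[[1L]]
  consensus <- inherits(target, "consensus_target")
  blocked <- if (consensus) ch == "-" else ch == "N"
  deg <- if (consensus) iupac_degeneracy(ch) else rep(1L, L)
  starts <- integer(); ends <- integer(); nexps <- integer()
  for (start in window_start:window_end) {
    for (len in params$len_min:params$len_max) {
      end <- start + len
      if (end > L) next
      idx <- (start + 1L):end
      if (any(blocked[idx])) next
      nexp <- prod(deg[idx])
      if (nexp > params$max_expansion) next
      starts <- c(starts, start); ends <- c(ends, end)
      nexps <- c(nexps, as.integer(nexp))
    }
  }
  if (!length(starts)) {
    return(data.frame(start = integer(), end = integer(),
                      target_subseq = character(), tm = numeric(),
                      tm_in_range = logical(), n_expansions = integer(),
                      stringsAsFactors = FALSE))
  }
  subs <- substring(target$seq, starts + 1L, ends)
  tm <- vapply(seq_along(subs), function(i) {
    if (nexps[i] > 1L) wildcard_tm(subs[i], cfg)
    else melting_temperature(subs[i], cfg)
  }, numeric(1L))
  data.frame(start = starts, end = ends, target_subseq = subs, tm = tm,
             tm_in_range = tm >= params$tm_min & tm <= params$tm_max,
             n_expansions = nexps, stringsAsFactors = FALSE)
}

#' Terminal adjustment of the maximum untiled gap
#'
#' Near the 3' end of a target the full `max_gap` can no longer be spent
#' before the next oligo without stranding an untiled tail longer than
#' `max_gap`. With `n` the minimal number of oligos still needed (computed
#' with the longest allowed oligo,
#' `n = ceiling((remaining - max_gap) / (len_max + max_gap))`, floored at
#' zero), the effective gap balances the slack over the remaining gaps
#' conservatively, assuming the shortest allowed oligos:
#' `min(max_gap, floor((remaining - n * len_min) / (n + 1)))` when `n > 0`,
#' and the remainder itself when it already fits within `max_gap`. Far from
#' the end this is exactly `max_gap`; close to the end it shrinks so the
#' tail stays compliant.
#'
#' @param remaining_length Untiled sequence remaining downstream, nt (>= 0).
#' @param params A [tiling_params()].
#' @return The effective maximum gap (nt) usable before the next oligo.
#' @examples
#' effective_max_gap(25, tiling_params())    # 25: tail needs no oligo
#' effective_max_gap(1000, tiling_params())  # 30: far from the end
#' @export
effective_max_gap <- function(remaining_length, params) {
  r <- as.integer(remaining_length)
  stopifnot(r >= 0L)
  mg <- params$max_gap
  if (r <= mg) return(r)
  n <- max(0L, as.integer(ceiling((r - mg) / (params$len_max + mg))))
  if (n == 0L) return(r)
  max(0L, min(mg, as.integer(floor((r - n * params$len_min) / (n + 1L)))))
}

# Deterministic candidate selection for the greedy phase. Prefers in-range
# Tm with the largest start; ties by longer oligo (a longer in-range oligo
# covers more and pushes the next window further, serving the greedy
# maximum-distance objective), then Tm closest to the range midpoint, then
# lexicographically smaller target subsequence. If no candidate is in
# range, the one with Tm closest to the range (preferring larger start,
# then longer) is returned with `fallback = TRUE`.
choose_candidate <- function(cands, params) {
  mid <- (params$tm_min + params$tm_max) / 2
  inr <- cands[cands$tm_in_range, , drop = FALSE]
  if (nrow(inr)) {
    ord <- order(-inr$start, -(inr$end - inr$start), abs(inr$tm - mid),
                 inr$target_subseq)
    out <- inr[ord[1L], , drop = FALSE]
    out$fallback <- FALSE
  } else {
    d <- tm_range_distance(cands$tm, params$tm_min, params$tm_max)
    ord <- order(d, -cands$start, -(cands$end - cands$start),
                 cands$target_subseq)
    out <- cands[ord[1L], , drop = FALSE]
    out$fallback <- TRUE
  }
  out
}

make_tiling_result <- function(target, oligos, flags) {
  if (nrow(oligos)) {
    oligos <- oligos[order(oligos$start), , drop = FALSE]
    rownames(oligos) <- NULL
    gaps <- c(oligos$start[1L],
              if (nrow(oligos) > 1L)
                oligos$start[-1L] - oligos$end[-nrow(oligos)],
              target$length - oligos$end[nrow(oligos)])
  } else {
    gaps <- target$length
  }
  structure(list(target_id = target$id, target = target,
                 target_length = target$length, oligos = oligos,
                 gaps = as.integer(gaps),
                 bases_tiled = sum(oligos$end - oligos$start),
                 flags = flags),
            class = "tiling_result")
}

#' @export
print.tiling_result <- function(x, ...) {
  cat(sprintf("<tiling_result> %s: %d oligos tiling %d/%d nt (max gap %s)\n",
              x$target_id, nrow(x$oligos), x$bases_tiled, x$target_length,
              if (length(x$gaps)) max(x$gaps) else NA))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Greedy left-to-right gapped tiling of one target
#'
#' Places oligos left to right so that each is the maximum distance from the
#' previously placed oligo (the 5' end acts as a virtual previous oligo
#' ending at coordinate 0) while keeping Tm and length within the configured
#' ranges and no untiled run longer than `max_gap`. The allowed gap shrinks
#' near the 3' end ([effective_max_gap()]) so the tail also complies. When no
#' candidate in the window has an in-range Tm, the candidate with Tm closest
#' to the range is retained and flagged; when a window admits no candidate
#' at all (e.g. a long run of `N`), the earliest downstream placement is
#' used and the oversized gap is flagged.
#'
#' @param target A [target_seq()] (or consensus target).
#' @param params A [tiling_params()].
#' @param cfg A [thermo_config()].
#' @return A `tiling_result`: ordered non-overlapping `oligos` (data.frame,
#'   0-based half-open coordinates, antisense DNA sequences 5'->3'), the
#'   untiled `gaps` (head, internal, tail), `bases_tiled` and any `flags`.
#' @examples
#' t <- make_synthetic_target(300, gc = 0.55, seed = 1)
#' greedy_tile(t, tiling_params(), thermo_config())
#' @export
greedy_tile <- function(target, params = tiling_params(),
                        cfg = thermo_config()) {
  stopifnot(inherits(target, "target_seq"), inherits(params, "tiling_params"),
            inherits(cfg, "thermo_config"))
  L <- target$length
  flags <- character()
  if (L < params$len_min) {
    return(make_tiling_result(target, empty_oligos(),
                              sprintf("target '%s' shorter than len_min (%d < %d)",
                                      target$id, L, params$len_min)))
  }
  oligos <- empty_oligos()
  prev_end <- 0L
  repeat {
    remaining <- L - prev_end
    if (remaining <= params$max_gap) break
    g_eff <- effective_max_gap(remaining, params)
    hi <- min(prev_end + g_eff, L)
    cands <- enumerate_candidates(target, prev_end, hi, params, cfg)
    oversized <- FALSE
    if (!nrow(cands)) {
      scan_hi <- L - params$len_min
      if (scan_hi >= prev_end) {
        all_c <- enumerate_candidates(target, prev_end, scan_hi, params, cfg)
      } else {
        all_c <- cands
      }
      if (!nrow(all_c)) {
        flags <- c(flags,
                   sprintf("untiled region [%d,%d) exceeds max_gap: no placeable oligo",
                           prev_end, L))
        break
      }
      smin <- min(all_c$start)
      cands <- all_c[all_c$start == smin, , drop = FALSE]
      oversized <- TRUE
    }
    pick <- choose_candidate(cands, params)
    if (oversized || pick$start - prev_end > params$max_gap) {
      flags <- c(flags, sprintf("gap of %d nt before position %d exceeds max_gap",
                                pick$start - prev_end, pick$start))
    }
    if (pick$fallback) {
      flags <- c(flags,
                 sprintf("oligo at %d retained with out-of-range Tm %.2f",
                         pick$start, pick$tm))
    }
    oligos <- rbind(oligos, oligo_row(target$id, pick, params))
    prev_end <- pick$end
  }
  if (!nrow(oligos) && !length(flags)) {
    flags <- sprintf("target '%s' needs no oligo (length <= max_gap)",
                     target$id)
  }
  make_tiling_result(target, oligos, flags)
}

#' Gap-balancing refinement of a tiling
#'
#' Second phase of the design: each oligo may move, and change length within
#' the allowed range, inside the span bounded by its two neighbours, to
#' maximize its smaller flanking gap while staying inside the ideal Tm
#' range. A move is accepted only if the oligo's min flanking gap strictly
#' improves, neither neighbour's min flanking gap drops below its
#' pre-refinement value, and no flanking gap grows beyond `max_gap` (or its
#' already-flagged size). Oligos whose Tm was out of range (flagged
#' fallbacks) are left untouched. Left-to-right passes repeat until a
#' fixpoint, capped at 5 passes. Oligo count is never changed.
#'
#' @param result A `tiling_result` from [greedy_tile()].
#' @param params A [tiling_params()].
#' @param cfg A [thermo_config()].
#' @return The refined `tiling_result`.
#' @export
refine_tiling <- function(result, params = tiling_params(),
                          cfg = thermo_config()) {
  stopifnot(inherits(result, "tiling_result"))
  ol <- result$oligos
  n <- nrow(ol)
  if (n == 0L) return(result)
  target <- result$target
  L <- result$target_length
  mid <- (params$tm_min + params$tm_max) / 2
  flank_lo <- function(i) if (i > 1L) ol$end[i - 1L] else 0L
  flank_hi <- function(i) if (i < n) ol$start[i + 1L] else L
  min_flank <- function(i) min(ol$start[i] - flank_lo(i),
                               flank_hi(i) - ol$end[i])
  baseline <- vapply(seq_len(n), min_flank, numeric(1L))
  for (pass in seq_len(5L)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!ol$tm_in_range[i]) next
      lo <- flank_lo(i); hi <- flank_hi(i)
      win_hi <- hi - params$len_min
      if (win_hi < lo) next
      cands <- enumerate_candidates(target, lo, win_hi, params, cfg)
      cands <- cands[cands$end <= hi & cands$tm_in_range, , drop = FALSE]
      if (!nrow(cands)) next
      cur <- min_flank(i)
      up <- cands$start - lo
      down <- hi - cands$end
      mg <- pmin(up, down)
      ok <- mg > cur &
        up <= max(params$max_gap, ol$start[i] - lo) &
        down <= max(params$max_gap, hi - ol$end[i])
      if (i > 1L) {
        prev_other <- ol$start[i - 1L] - flank_lo(i - 1L)
        ok <- ok & pmin(prev_other, up) >= baseline[i - 1L]
      }
      if (i < n) {
        next_other <- flank_hi(i + 1L) - ol$end[i + 1L]
        ok <- ok & pmin(next_other, down) >= baseline[i + 1L]
      }
      if (!any(ok)) next
      cands <- cands[ok, , drop = FALSE]
      mg <- mg[ok]
      ord <- order(-mg, abs(cands$tm - mid), -cands$start,
                   -(cands$end - cands$start), cands$target_subseq)
      pick <- cands[ord[1L], , drop = FALSE]
      pick$fallback <- FALSE
      keep_class <- ol$oligo_class[i]
      ol[i, ] <- oligo_row(ol$target_id[i], pick, params, keep_class)
      changed <- TRUE
    }
    if (!changed) break
  }
  make_tiling_result(target, ol, result$flags)
}

#' Design oligos for a single target (greedy tiling + refinement)
#'
#' Convenience wrapper running [greedy_tile()] then [refine_tiling()].
#'
#' @inheritParams greedy_tile
#' @return A refined `tiling_result`.
#' @examples
#' t <- make_synthetic_target(500, gc = 0.55, seed = 7)
#' design_oligos(t)
#' @export
design_oligos <- function(target, params = tiling_params(),
                          cfg = thermo_config()) {
  refine_tiling(greedy_tile(target, params, cfg), params, cfg)
}

#' End-to-end fixed-length tiling baseline
#'
#' The traditional depletion design: cover each target completely with
#' fixed-length oligos (default 50 nt), the last oligo sliding back to end
#' flush with the target. Used as the cost/footprint baseline against which
#' the gapped design is compared.
#'
#' @param target_lengths Integer vector of target lengths, nt (each >= 1).
#' @param oligo_len Baseline oligo length, nt.
#' @return list with `n_oligos` (total count, `ceiling(L / oligo_len)` per
#'   target) and `bases` (total bases covered, the summed target lengths).
#' @examples
#' tile_end_to_end(c(4082, 1825, 162, 120, 1631, 819))
#' @export
tile_end_to_end <- function(target_lengths, oligo_len = 50L) {
  stopifnot(all(target_lengths >= 1L), oligo_len >= 1L)
  list(n_oligos = as.integer(sum(ceiling(target_lengths / oligo_len))),
       bases = as.integer(sum(target_lengths)))
}
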