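cfg <- thermo_config()
par0 <- tiling_params()

test_that("candidate enumeration matches a brute-force double loop", {
  t <- make_synthetic_target(200, gc = 0.5, seed = 3)
  # plant an N to exercise exclusion
  substr(t$seq, 101, 101) <- "N"

  brute <- function(ws, we) {
    out <- list()
    for (s in ws:we) for (len in par0$len_min:par0$len_max) {
      e <- s + len
      if (e > t$length) next
      if (grepl("N", substr(t$seq, s + 1, e), fixed = TRUE)) next
      out[[length(out) + 1L]] <- c(s, e)
    }
    do.call(rbind, out)
  }
  for (win in list(c(0, 160), c(0, 0), c(90, 110), c(195, 200))) {
    got <- enumerate_candidates(t, win[1], win[2], par0, cfg)
    exp <- brute(win[1], win[2])
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(exp))
    }
  }
  # forced position: zero-width window, fixed length
  p1 <- tiling_params(len_min = 40, len_max = 40)
  expect_equal(nrow(enumerate_candidates(t, 10, 10, p1, cfg)), 1L)
  # window width 5, two lengths: at most 12 candidates
  expect_lte(nrow(enumerate_candidates(t, 0, 5, par0, cfg)), 12L)
})

test_that("effective max gap never strands a non-compliant tail", {
  expect_equal(effective_max_gap(25, par0), 25)
  expect_equal(effective_max_gap(1000, par0), 30)
  g71 <- effective_max_gap(71, par0)
  expect_lt(g71, 30)
  # enumeration oracle: at every remainder, placing the next oligo at the
  # maximum-distance offset g_eff with the preferred (longest fitting)
  # length admits a completion with no untiled run beyond max_gap
  memo <- new.env()
  admits_completion <- function(r) {
    key <- as.character(r)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (r <= par0$max_gap) TRUE
    else if (r < par0$len_min) FALSE
    else {
      g <- effective_max_gap(r, par0)
      ok <- FALSE
      for (len in par0$len_max:par0$len_min) {
        if (g + len > r) next
        ok <- admits_completion(r - g - len)
        break
      }
      ok
    }
    memo[[key]] <- res
    res
  }
  for (r in c(39:45, 69:75, 100, 139, 140, 141, 200, 500, 1000)) {
    expect_true(admits_completion(r), label = paste("remaining", r))
  }
  # near-terminal case: remaining 71 forces the last oligo to leave a
  # compliant tail when placed at maximum distance
  for (len in 39:40) expect_lte(71 - g71 - len, 30)
})

test_that("greedy tiling satisfies the interval checker on random targets", {
  t40 <- target_seq("t40", strrep("A", 40))
  r40 <- greedy_tile(t40, par0, cfg)
  expect_equal(nrow(r40$oligos), 1L)
  expect_equal(c(r40$oligos$start, r40$oligos$end), c(0L, 40L))
  expect_equal(r40$gaps, c(0L, 0L))

  t500 <- make_synthetic_target(500, gc = 0.45, seed = 7)
  r500 <- greedy_tile(t500, par0, cfg)
  expect_length(check_tiling(r500, par0), 0L)
  expect_gt(nrow(r500$oligos), 1L)
  expect_true(all(r500$gaps <= par0$max_gap))
  # determinism
  expect_identical(r500$oligos, greedy_tile(t500, par0, cfg)$oligos)

  for (s in 0:24) {
    t <- make_synthetic_target(120 + 17 * s, gc = 0.42 + 0.006 * s, seed = s)
    expect_length(check_tiling(greedy_tile(t, par0, cfg), par0), 0L)
  }
})

test_that("degenerate targets yield flagged empty or gapped tilings", {
  short <- target_seq("short", strrep("A", 20))
  rs <- greedy_tile(short, par0, cfg)
  expect_equal(nrow(rs$oligos), 0L)
  expect_match(rs$flags, "shorter", all = FALSE)

  alln <- target_seq("alln", strrep("N", 200))
  rn <- greedy_tile(alln, par0, cfg)
  expect_equal(nrow(rn$oligos), 0L)
  expect_length(rn$flags, 1L)

  # a long N run forces a flagged oversized gap, not an error
  withN <- target_seq("withN", paste0(strrep("A", 80), strrep("N", 50),
                                      strrep("A", 80)))
  rN <- greedy_tile(withN, par0, cfg)
  expect_gt(nrow(rN$oligos), 0L)
  expect_match(rN$flags, "exceeds max_gap", all = FALSE)
})

test_that("refinement balances gaps without harming any oligo", {
  # no freedom: single oligo covering the whole target
  t40 <- target_seq("t40", strrep("A", 40))
  r40 <- greedy_tile(t40, par0, cfg)
  expect_identical(refine_tiling(r40, par0, cfg)$oligos, r40$oligos)

  # three 40-mers on a uniform-Tm poly(A) target with gaps (0, 30, 0, 30):
  # refinement must strictly improve the middle oligo's min flanking gap
  # and rebalance the gap profile
  tu <- target_seq("uniform", strrep("A", 180))
  ol <- do.call(rbind, lapply(c(0L, 70L, 110L), function(s) {
    data.frame(id = paste0("uniform_", s + 1L, "_40"),
               target_id = "uniform", start = s, end = s + 40L,
               antisense_seq = strrep("T", 40), tm =
                 melting_temperature(strrep("A", 40), cfg),
               tm_in_range = TRUE, oligo_class = "individual",
               n_expansions = 1L, stringsAsFactors = FALSE)
  }))
  manual <- oligotiler:::make_tiling_result(tu, ol, character())
  expect_equal(manual$gaps, c(0L, 30L, 0L, 30L))
  ref <- refine_tiling(manual, par0, cfg)
  expect_gt(min_flank_gaps(ref)[2], min_flank_gaps(manual)[2])
  expect_true(all(min_flank_gaps(ref) >= min_flank_gaps(manual)))
  # gaps end up more balanced: the spread shrinks
  expect_lt(stats::sd(ref$gaps), stats::sd(manual$gaps))
  expect_length(check_tiling(ref, par0), 0L)

  # property: over 100 random fixtures no oligo's min flanking gap shrinks
  # and in-range Tm stays in range
  for (s in 0:99) {
    t <- make_synthetic_target(150 + 7 * s, gc = 0.40 + 0.0015 * s, seed = s)
    g <- greedy_tile(t, par0, cfg)
    r <- refine_tiling(g, par0, cfg)
    expect_equal(nrow(r$oligos), nrow(g$oligos))
    if (nrow(g$oligos) == 0) next
    expect_true(all(min_flank_gaps(r) >= min_flank_gaps(g)))
    expect_true(all(!g$oligos$tm_in_range | r$oligos$tm_in_range))
    expect_length(check_tiling(r, par0), 0L)
  }
})

test_that("end-to-end baseline arithmetic", {
  # six rRNA target lengths derived from inclusive coordinate ranges
  xl <- c(4082, 1825, 162, 120, 1631, 819)
  base <- tile_end_to_end(xl, 50)
  expect_equal(base$n_oligos, 176L)
  expect_equal(base$bases, 8639L)
  expect_equal(tile_end_to_end(50), list(n_oligos = 1L, bases = 50L))
  expect_equal(tile_end_to_end(51), list(n_oligos = 2L, bases = 51L))
})
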