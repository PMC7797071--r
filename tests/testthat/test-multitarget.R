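cfg <- thermo_config()
par0 <- tiling_params()

test_that("wildcard expansion is the sorted Cartesian product", {
  expect_equal(expand_wildcards("ACGT"), "ACGT")
  # one R and one Y in a 10-mer: four sequences, all combinations
  ex <- expand_wildcards("ACGRTTYACG")
  expect_length(ex, 4L)
  expect_setequal(ex, c("ACGATTCACG", "ACGATTTACG",
                        "ACGGTTCACG", "ACGGTTTACG"))
  expect_identical(ex, sort(ex))
  expect_length(expand_wildcards("RYN"), 16L)
  # RNA input expands with U
  expect_setequal(expand_wildcards("RU"), c("AU", "GU"))
  expect_error(expand_wildcards("AC!G"), "position 3")
})

test_that("consensus building follows the IUPAC column rules", {
  a <- alignment(c("x", "y"), c("ACGUA", "ACGUA"))
  cons <- build_consensus(a)
  expect_equal(cons$seq, "ACGUA")
  expect_equal(cons$degeneracy, rep(1L, 5))

  b <- alignment(c("x", "y"), c("ACAUA", "ACGUA"))
  cb <- build_consensus(b)
  expect_equal(substr(cb$seq, 3, 3), "R")
  expect_equal(cb$degeneracy[3], 2L)
  # without wildcards the mismatch column is masked
  expect_equal(substr(build_consensus(b, allow_wildcards = FALSE)$seq, 3, 3),
               "-")

  # gap columns are masked and never covered by any candidate
  g <- alignment(c("x", "y"),
                 c(paste0(strrep("A", 50), "-", strrep("A", 49)),
                   strrep("A", 100)))
  cg <- build_consensus(g)
  expect_equal(substr(cg$seq, 51, 51), "-")
  cand <- enumerate_candidates(cg, 0, cg$length, par0, cfg)
  expect_true(all(cand$end <= 50 | cand$start >= 51))

  expect_error(alignment(c("x", "y"), c("ACG", "AC")), "unequal")
})

test_that("exact reuse finds all and only complementary loci", {
  t1 <- make_synthetic_target(300, gc = 0.5, seed = 13)
  d1 <- design_oligos(t1, par0, cfg)
  expect_gt(nrow(d1$oligos), 1L)

  # self-match: every oligo is found at its own locus
  self <- find_exact_reuse(d1$oligos, t1)
  expect_true(all(paste(d1$oligos$start, d1$oligos$end) %in%
                    paste(self$start, self$end)))

  # planted mutation inside oligo #2's footprint breaks only that match
  s2 <- d1$oligos$start[2] + 5L
  mut <- t1$seq
  substr(mut, s2 + 1L, s2 + 1L) <- setdiff(c("A", "C", "G", "U"),
                                           substr(mut, s2 + 1L, s2 + 1L))[1]
  t2 <- target_seq("mutant", mut)
  hits <- find_exact_reuse(d1$oligos, t2)
  expect_false(d1$oligos$id[2] %in% hits$oligo_id)
  expect_true(all(setdiff(d1$oligos$id, d1$oligos$id[2]) %in%
                    hits$oligo_id))

  # an absent oligo yields no loci
  foreign <- d1$oligos[1, , drop = FALSE]
  foreign$antisense_seq <- strrep("T", 39)
  expect_equal(nrow(find_exact_reuse(foreign, t1)), 0L)
})

test_that("unaligned shared design reuses, stays compact and accounts", {
  # identical pair: the second target is fully covered by reuse
  t <- make_synthetic_target(400, gc = 0.45, seed = 3)
  ident <- shared_tile_unaligned(list(target_seq("a", t$seq),
                                      target_seq("b", t$seq)), par0, cfg)
  cc <- ident$class_counts
  expect_equal(cc$wildcard, 0L)
  expect_equal(unname(cc$unique), c(0L, 0L))
  expect_equal(cc$total_distinct, cc$common)

  # divergent pair at ~86%: strictly fewer oligos than two independents
  pair <- make_divergent_pair(1500, identity = 0.86, seed = 5)
  ta <- target_seq("variant_a", unname(pair$degapped["variant_a"]))
  tb <- target_seq("variant_b", unname(pair$degapped["variant_b"]))
  sh <- shared_tile_unaligned(list(ta, tb), par0, cfg)
  indep <- nrow(design_oligos(ta, par0, cfg)$oligos) +
    nrow(design_oligos(tb, par0, cfg)$oligos)
  expect_lt(sh$class_counts$total_distinct, indep)
  for (tr in sh$per_target) expect_length(check_tiling(tr, par0), 0L)

  # unrelated targets share no 39-mers: designs equal the independents
  u1 <- make_synthetic_target(350, gc = 0.45, seed = 31)
  u2 <- make_synthetic_target(350, gc = 0.55, seed = 32)
  un <- shared_tile_unaligned(list(u1, u2), par0, cfg)
  expect_equal(un$class_counts$common, 0L)
  expect_equal(unname(un$class_counts$unique),
               c(nrow(design_oligos(u1, par0, cfg)$oligos),
                 nrow(design_oligos(u2, par0, cfg)$oligos)))

  expect_error(shared_tile_unaligned(list(t)), "2 targets")
})

test_that("aligned shared design classifies oligos like a brute-force checker", {
  pair <- make_divergent_pair(1200, identity = 0.98, seed = 9)
  sh <- shared_tile_aligned(pair, par0, cfg)
  cc <- sh$class_counts

  # brute-force classification: re-match every emitted oligo to both rows
  rows <- lapply(pair$ids, function(id) target_seq(id, pair$degapped[[id]]))
  names(rows) <- pair$ids
  for (pool in names(sh$per_target)) {
    ol <- sh$per_target[[pool]]$oligos
    for (i in seq_len(nrow(ol))) {
      fp <- substr(rows[[pool]]$seq, ol$start[i] + 1L, ol$end[i])
      expansions <- expand_wildcards(
        reverse_complement(ol$antisense_seq[i], "RNA"))
      # footprint complementarity in this pool
      expect_true(chartr("T", "U", fp) %in% expansions)
      n_match <- sum(vapply(rows, function(rt) {
        nrow(find_exact_reuse(ol[i, , drop = FALSE], rt)) > 0
      }, logical(1L)))
      if (ol$oligo_class[i] %in% c("common", "wildcard")) {
        expect_equal(n_match, 2L, label = ol$id[i])
      }
      if (ol$oligo_class[i] == "common") {
        expect_equal(ol$n_expansions[i], 1L)
      }
      if (ol$oligo_class[i] == "wildcard") {
        expect_gt(ol$n_expansions[i], 1L)
        expect_lte(ol$n_expansions[i], par0$max_expansion)
      }
    }
    expect_length(check_tiling(sh$per_target[[pool]], par0), 0L)
  }
  expect_gt(cc$common, 0L)
  expect_equal(unname(cc$pool_sizes),
               unname(cc$common + cc$wildcard + cc$unique))

  # identical rows: everything common
  t <- make_synthetic_target(500, gc = 0.5, seed = 17)
  ident <- shared_tile_aligned(alignment(c("a", "b"), c(t$seq, t$seq)),
                               par0, cfg)
  expect_equal(ident$class_counts$wildcard, 0L)
  expect_equal(sum(ident$class_counts$unique), 0L)
})

test_that("alignment column maps are bijective on non-gap columns", {
  aln <- alignment(c("x", "y"), c("AC-GU-A", "ACAGUUA"))
  for (id in aln$ids) {
    m <- aln$column_maps[[id]]
    nongap <- m[!is.na(m)]
    expect_equal(sort(nongap), seq_along(nongap) - 1L)
    # round trip: ungapped coordinate -> column -> ungapped coordinate
    cols <- match(nongap, m)
    expect_equal(m[cols], nongap)
  }
})

test_that("class accounting rejects inconsistent manifests", {
  t <- make_synthetic_target(400, gc = 0.45, seed = 3)
  sh <- shared_tile_unaligned(list(target_seq("a", t$seq),
                                   target_seq("b", t$seq)), par0, cfg)
  expect_silent(classify_oligos(sh))
  broken <- sh
  broken$per_target[[2]]$oligos <- broken$per_target[[2]]$oligos[-1, ]
  expect_error(classify_oligos(broken), "inconsistent manifest")
})
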