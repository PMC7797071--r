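# IUPAC nucleotide codes. Sets are stored with DNA letters; U is mapped to
# T on entry and restored on output when the input looks like RNA.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# code for a set of observed bases (DNA letters, any order)
iupac_code_for <- local({
  rev_map <- NULL
  function(bases) {
    if (is.null(rev_map)) {
      rev_map <<- stats::setNames(
        names(IUPAC_SETS),
        vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
               character(1L)))
    }
    key <- paste(sort(unique(bases)), collapse = "")
    code <- rev_map[key]
    if (is.na(code)) stop("no IUPAC code for base set: ", key)
    unname(code)
  }
})

# per-character degeneracy; gaps/masks count as 1 (they are excluded from
# candidates before degeneracy matters)
iupac_degeneracy <- function(chars) {
  sizes <- c(vapply(IUPAC_SETS, length, integer(1L)),
             U = 1L, "-" = 1L)
  out <- sizes[chars]
  if (anyNA(out)) {
    stop("invalid IUPAC character '", chars[which(is.na(out))[1L]], "'")
  }
  as.integer(unname(out))
}

#' Expand an IUPAC-degenerate sequence into unambiguous sequences
#'
#' Full Cartesian expansion of every wildcard position, e.g. an oligo with
#' one R and one Y expands to the four sequences covering all combinations.
#' The result is sorted lexicographically and has length equal to the
#' product of per-position degeneracies.
#'
#' @param seq IUPAC nucleotide string (DNA or RNA; output letters follow the
#'   input alphabet, U-containing input expands with U).
#' @return Character vector of unambiguous sequences.
#' @examples
#' expand_wildcards("ACGT")  # itself
#' expand_wildcards("RYN")   # 2 * 2 * 4 = 16 sequences
#' @export
expand_wildcards <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  rna <- grepl("U", s, fixed = TRUE) && !grepl("T", s, fixed = TRUE)
  s <- chartr("U", "T", s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  }
  sets <- IUPAC_SETS[ch]
  n_exp <- prod(lengths(sets))
  if (n_exp > 65536) stop("expansion too large (", n_exp, " sequences)")
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  out <- sort(do.call(paste0, grid))
  if (rna) out <- chartr("T", "U", out)
  out
}

#' Build the (possibly degenerate) consensus of an alignment
#'
#' Columns identical across rows keep their base; mismatch columns receive
#' the IUPAC code covering exactly the observed bases (when
#' `allow_wildcards`) or are masked; any column containing a gap in any row
#' is masked (`-`). Masked columns are never covered by a candidate oligo.
#' Per-column degeneracy (the number of observed bases) is recorded and
#' drives the wildcard-expansion threshold during consensus tiling.
#'
#' @param aln An [alignment()].
#' @param allow_wildcards Encode mismatch columns as IUPAC wildcards? If
#'   `FALSE` they are masked instead.
#' @param max_expansion Default per-oligo expansion bound carried along for
#'   downstream tiling (the per-column consensus itself is not thresholded).
#' @return A consensus target (classes `consensus_target`, `target_seq`)
#'   with fields `id`, `seq`, `length`, `degeneracy` and `max_expansion`.
#' @examples
#' a <- alignment(c("x", "y"), c("ACGUA", "ACAUA"))
#' build_consensus(a)$seq  # "ACRUA"
#' @export
build_consensus <- function(aln, allow_wildcards = TRUE, max_expansion = 2L) {
  stopifnot(inherits(aln, "alignment"))
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  width <- ncol(mat)
  cons <- character(width)
  deg <- integer(width)
  for (j in seq_len(width)) {
    col <- mat[, j]
    if (any(col == "-")) {
      cons[j] <- "-"; deg[j] <- 1L
      next
    }
    if (any(col == "N")) {
      bases <- c("A", "C", "G", "T")
    } else {
      bases <- unique(chartr("U", "T", col))
    }
    if (length(bases) == 1L) {
      cons[j] <- chartr("T", "U", bases); deg[j] <- 1L
    } else if (allow_wildcards) {
      cons[j] <- iupac_code_for(bases); deg[j] <- length(bases)
    } else {
      cons[j] <- "-"; deg[j] <- 1L
    }
  }
  structure(list(id = "consensus", seq = paste(cons, collapse = ""),
                 length = width, degeneracy = deg,
                 max_expansion = as.integer(max_expansion)),
            class = c("consensus_target", "target_seq"))
}

#' Find exact complementary matches of oligos in a target
#'
#' Locates every position of a target whose subsequence is exactly
#' complementary to one of the given antisense oligos (the footprint an
#' oligo was designed against). Wildcard oligos match a locus when any of
#' their expansions is exactly complementary there. Used to seed subsequent
#' targets with reusable oligos in unaligned shared-pool design.
#'
#' @param oligos Oligo data.frame from a `tiling_result` (internal 0-based
#'   layout with `antisense_seq` and `n_expansions` columns).
#' @param target A [target_seq()].
#' @return data.frame with columns `oligo_id`, `start`, `end` (0-based
#'   half-open on `target`), one row per matched locus, ordered by `start`.
#' @export
find_exact_reuse <- function(oligos, target) {
  stopifnot(inherits(target, "target_seq"))
  subject <- Biostrings::DNAString(chartr("U", "T", target$seq))
  out <- list()
  for (i in seq_len(nrow(oligos))) {
    fp <- reverse_complement(oligos$antisense_seq[i], "DNA")
    fixed <- if (oligos$n_expansions[i] > 1L) "subject" else TRUE
    hits <- Biostrings::matchPattern(Biostrings::DNAString(fp), subject,
                                     fixed = fixed)
    if (length(hits)) {
      out[[length(out) + 1L]] <-
        data.frame(oligo_id = oligos$id[i],
                   start = Biostrings::start(hits) - 1L,
                   end = Biostrings::end(hits),
                   row = i, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(oligo_id = character(), start = integer(),
                      end = integer(), row = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Greedily keep non-overlapping placements (sorted by start; earlier wins).
drop_overlaps <- function(pl) {
  keep <- logical(nrow(pl))
  cur_end <- 0L
  for (i in seq_len(nrow(pl))) {
    if (pl$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- pl$end[i]
    }
  }
  pl[keep, , drop = FALSE]
}

# Tile the untiled complement of `placed` intervals on `target`; returns the
# extra oligo rows (class "unique") plus flags for non-compliant gaps.
tile_residuals <- function(target, placed, params, cfg) {
  L <- target$length
  region_start <- c(0L, placed$end)      # untiled region k: [start, end)
  region_end <- c(placed$start, L)
  oligos <- empty_oligos()
  flags <- character()
  for (k in seq_along(region_start)) {
    a <- region_start[k]; b <- region_end[k]
    if (b - a <= params$max_gap) next
    sub <- target_seq(target$id, substring(target$seq, a + 1L, b))
    res <- design_oligos(sub, params, cfg)
    if (nrow(res$oligos)) {
      ol <- res$oligos
      ol$start <- ol$start + a
      ol$end <- ol$end + a
      ol$id <- oligo_name(target$id, ol$start, ol$end - ol$start,
                          ol$n_expansions > 1L)
      ol$oligo_class <- "unique"
      oligos <- rbind(oligos, ol)
    }
    if (length(res$flags)) {
      flags <- c(flags, paste0(sprintf("region [%d,%d): ", a, b), res$flags))
    }
  }
  list(oligos = oligos, flags = flags)
}

make_shared_design <- function(per_target) {
  manifests <- lapply(per_target, function(tr) tr$oligos$id)
  design <- structure(list(per_target = per_target,
                           pool_manifests = manifests,
                           class_counts = NULL),
                      class = "shared_design")
  design$class_counts <- classify_oligos(design)
  design
}

#' @export
print.shared_design <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf("<shared_design> %d pools, %d distinct oligos (%d common, %d wildcard)\n",
              length(x$per_target), cc$total_distinct, cc$common,
              cc$wildcard))
  for (id in names(x$per_target)) {
    cat(sprintf("  %s: %d oligos (%d unique)\n", id,
                length(x$pool_manifests[[id]]), cc$unique[[id]]))
  }
  invisible(x)
}

#' Shared oligo pools across unaligned targets
#'
#' Tiling proceeds normally for the first target. Each subsequent target is
#' first seeded with oligos from the first design that have exact
#' complementary matches (class `common`); the remaining untiled regions are
#' then tiled independently (class `unique`). A first-design oligo counts as
#' common only when it is placed in every target; all exact-match loci of a
#' reused oligo are marked tiled.
#'
#' @param targets List of two or more [target_seq()] objects with unique
#'   ids.
#' @param params A [tiling_params()].
#' @param cfg A [thermo_config()].
#' @return A `shared_design`: per-target `tiling_result`s, pool manifests
#'   and class counts satisfying
#'   `pool size == common + wildcard + unique(pool)`.
#' @examples
#' pair <- make_divergent_pair(600, identity = 0.9, seed = 5)
#' ts <- lapply(seq_along(pair$ids),
#'              function(i) target_seq(pair$ids[i], pair$degapped[[i]]))
#' shared_tile_unaligned(ts, tiling_params(), thermo_config())
#' @export
shared_tile_unaligned <- function(targets, params = tiling_params(),
                                  cfg = thermo_config()) {
  if (length(targets) < 2L) {
    stop("shared design needs >= 2 targets; use design_oligos() for one")
  }
  ids <- vapply(targets, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate target ids")
  first <- design_oligos(targets[[1L]], params, cfg)
  fol <- first$oligos
  rest <- targets[-1L]
  # candidate reuse loci of every first-design oligo in every later target
  locus_tabs <- lapply(rest, function(t) find_exact_reuse(fol, t))
  eligible <- fol$id
  for (lt in locus_tabs) eligible <- intersect(eligible, lt$oligo_id)
  # a reused oligo must be placeable (non-overlapping) in every later
  # target; shrink the eligible set until placements are stable
  placements <- NULL
  repeat {
    placements <- lapply(locus_tabs, function(lt) {
      drop_overlaps(lt[lt$oligo_id %in% eligible, , drop = FALSE])
    })
    placed_everywhere <- eligible
    for (pl in placements) {
      placed_everywhere <- intersect(placed_everywhere, pl$oligo_id)
    }
    if (length(placed_everywhere) == length(eligible)) break
    eligible <- placed_everywhere
  }
  fol$oligo_class <- ifelse(fol$id %in% eligible, "common", "unique")
  per_target <- list(make_tiling_result(targets[[1L]], fol, first$flags))
  for (k in seq_along(rest)) {
    t <- rest[[k]]
    pl <- placements[[k]]
    pl <- pl[pl$oligo_id %in% eligible, , drop = FALSE]
    seeded <- fol[pl$row, , drop = FALSE]
    if (nrow(seeded)) {
      seeded$start <- pl$start
      seeded$end <- pl$end
      seeded$target_id <- t$id
      seeded$oligo_class <- "common"
    }
    resid <- tile_residuals(t, pl, params, cfg)
    oligos <- rbind(seeded, resid$oligos)
    per_target[[k + 1L]] <- make_tiling_result(t, oligos, resid$flags)
  }
  names(per_target) <- ids
  make_shared_design(per_target)
}

#' Shared oligo pools from an alignment via wildcard consensus
#'
#' The consensus of the alignment ([build_consensus()]) is tiled first;
#' candidate consensus oligos spanning only identical columns become
#' `common` oligos, those spanning mismatch columns become `wildcard` oligos
#' (ordered as mixtures) and are retained only while their expansion count
#' stays within `params$max_expansion` — both kinds serve every row. Oligo
#' placements are mapped from alignment columns back to ungapped per-row
#' coordinates, and each row's remaining untiled regions are tiled
#' individually (class `unique`). Candidate oligos never span masked (gap)
#' columns.
#'
#' @param aln An [alignment()].
#' @param params A [tiling_params()].
#' @param cfg A [thermo_config()].
#' @return A `shared_design` (see [shared_tile_unaligned()]).
#' @examples
#' pair <- make_divergent_pair(600, identity = 0.98, seed = 9)
#' shared_tile_aligned(pair, tiling_params(), thermo_config())
#' @export
shared_tile_aligned <- function(aln, params = tiling_params(),
                                cfg = thermo_config()) {
  stopifnot(inherits(aln, "alignment"))
  cons <- build_consensus(aln, allow_wildcards = TRUE,
                          max_expansion = params$max_expansion)
  cons_res <- design_oligos(cons, params, cfg)
  col <- cons_res$oligos
  col$oligo_class <- ifelse(col$n_expansions > 1L, "wildcard", "common")
  per_target <- vector("list", length(aln$ids))
  for (r in seq_along(aln$ids)) {
    id <- aln$ids[r]
    row_target <- target_seq(id, aln$degapped[[id]])
    if (nrow(col)) {
      cmap <- aln$column_maps[[id]]
      row_start <- cmap[col$start + 1L]
      row_end <- cmap[col$end] + 1L
      seeded <- col
      seeded$target_id <- id
      seeded$start <- row_start
      seeded$end <- row_end
      pl <- data.frame(start = row_start, end = row_end)
    } else {
      seeded <- empty_oligos()
      pl <- data.frame(start = integer(), end = integer())
    }
    resid <- tile_residuals(row_target, pl, params, cfg)
    oligos <- rbind(seeded, resid$oligos)
    flags <- resid$flags
    if (row_target$length < params$len_min) {
      flags <- c(flags, sprintf("row '%s' shorter than len_min after degapping",
                                id))
    }
    per_target[[r]] <- make_tiling_result(row_target, oligos, flags)
  }
  names(per_target) <- aln$ids
  make_shared_design(per_target)
}

#' Class accounting of a shared design
#'
#' Counts common, wildcard and per-pool unique oligos and verifies the pool
#' arithmetic: every pool's size equals `common + wildcard + unique(pool)`,
#' and the number of distinct oligos equals
#' `common + wildcard + sum(unique)`.
#'
#' @param design A `shared_design`.
#' @return list with `common`, `wildcard`, `unique` (named integer vector,
#'   one entry per pool), `pool_sizes` and `total_distinct`.
#' @export
classify_oligos <- function(design) {
  stopifnot(inherits(design, "shared_design"))
  tabs <- lapply(design$per_target, function(tr) {
    tr$oligos[, c("id", "oligo_class"), drop = FALSE]
  })
  all_rows <- do.call(rbind, tabs)
  pool_ids <- names(design$per_target)
  common_ids <- unique(all_rows$id[all_rows$oligo_class == "common"])
  wildcard_ids <- unique(all_rows$id[all_rows$oligo_class == "wildcard"])
  n_pools <- length(tabs)
  for (cid in c(common_ids, wildcard_ids)) {
    present <- vapply(tabs, function(tb) cid %in% tb$id, logical(1L))
    if (!all(present)) {
      stop("inconsistent manifest: shared oligo '", cid,
           "' missing from some pools")
    }
  }
  uniq <- vapply(tabs, function(tb) {
    sum(tb$oligo_class == "unique")
  }, integer(1L))
  pool_sizes <- vapply(tabs, nrow, integer(1L))
  expected <- length(common_ids) + length(wildcard_ids) + uniq
  if (!all(pool_sizes == expected)) {
    stop("inconsistent manifest: pool size != common + wildcard + unique")
  }
  total_distinct <- length(unique(all_rows$id))
  if (total_distinct !=
      length(common_ids) + length(wildcard_ids) + sum(uniq)) {
    stop("inconsistent manifest: duplicated oligo ids across pools")
  }
  list(common = length(common_ids), wildcard = length(wildcard_ids),
       unique = stats::setNames(uniq, pool_ids),
       pool_sizes = stats::setNames(pool_sizes, pool_ids),
       total_distinct = total_distinct)
}
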