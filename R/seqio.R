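#' A single target RNA
#'
#' Light container for one target sequence, the substrate of oligo tiling.
#' The sequence is stored uppercase in the RNA alphabet (T is normalized to
#' U); `N` is permitted and is never covered by a designed oligo.
#'
#' @param id Non-empty identifier, unique within a run.
#' @param seq Sequence string (ACGU/T, may contain N).
#' @return An object of class `target_seq` with fields `id`, `seq`, `length`.
#' @examples
#' target_seq("rna1", "AUGGCUAAC")
#' @export
target_seq <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  s <- normalize_rna(seq, allow_n = TRUE)
  structure(list(id = id, seq = s, length = nchar(s)), class = "target_seq")
}

#' @export
print.target_seq <- function(x, ...) {
  cat(sprintf("<target_seq> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

#' A gapped multiple alignment of target variants
#'
#' Equal-length gapped rows (ACGU plus `-`) of two or more divergent target
#' RNAs, e.g. maternal and somatic rRNA variants. Per-row column maps give,
#' for every alignment column, the 0-based ungapped coordinate in that row
#' (`NA` at gap columns); they are bijective on non-gap columns and are used
#' to map consensus-oligo placements back to each variant.
#'
#' @param ids Character vector of row identifiers (unique, non-empty).
#' @param rows Character vector of equal-length gapped sequences.
#' @return An object of class `alignment` with fields `ids`, `rows`,
#'   `column_maps` (list of integer vectors) and `degapped` (ungapped rows).
#' @examples
#' alignment(c("a", "b"), c("AC-GU", "ACAGU"))
#' @export
alignment <- function(ids, rows) {
  stopifnot(is.character(ids), is.character(rows),
            length(ids) == length(rows))
  if (length(ids) < 2L) stop("an alignment needs >= 2 rows")
  if (anyDuplicated(ids)) stop("duplicate alignment row ids")
  rows <- vapply(rows, function(r) {
    r <- chartr("tT", "uU", r)
    toupper(r)
  }, character(1L), USE.NAMES = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(widths, collapse = ", "))
  }
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% c("A", "C", "G", "U", "N", "-"))
    if (length(bad)) {
      stop(sprintf("row '%s': invalid character '%s' at column %d",
                   ids[i], ch[bad[1L]], bad[1L]))
    }
  }
  column_maps <- lapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    m <- rep(NA_integer_, length(ch))
    m[ch != "-"] <- seq_len(sum(ch != "-")) - 1L
    m
  })
  names(column_maps) <- ids
  degapped <- vapply(rows, function(r) gsub("-", "", r, fixed = TRUE),
                     character(1L), USE.NAMES = FALSE)
  structure(list(ids = ids, rows = rows, column_maps = column_maps,
                 degapped = stats::setNames(degapped, ids),
                 width = widths[1L]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns: %s\n",
              length(x$ids), x$width, paste(x$ids, collapse = ", ")))
  invisible(x)
}

#' Reverse complement with full IUPAC support
#'
#' Complements every IUPAC code (R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H,
#' N<->N) and reverses, delegating to Biostrings. Double application (with
#' the alphabet mapped back) restores the input.
#'
#' @param seq IUPAC nucleotide string (RNA or DNA; gaps not allowed).
#' @param output_alphabet `"DNA"` (default) or `"RNA"` for the returned
#'   string.
#' @return The reverse complement, 5'->3', in the requested alphabet.
#' @examples
#' reverse_complement("ACGU")          # "ACGT"
#' reverse_complement("AR", "RNA")     # "YU"
#' @export
reverse_complement <- function(seq, output_alphabet = c("DNA", "RNA")) {
  output_alphabet <- match.arg(output_alphabet)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("uU", "tT", toupper(seq))
  rc <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    error = function(e) stop("invalid IUPAC character in sequence: ",
                             conditionMessage(e), call. = FALSE))
  if (output_alphabet == "RNA") rc <- chartr("T", "U", rc)
  rc
}

#' Read target sequences or an alignment from FASTA
#'
#' Parses FASTA through Biostrings; record ids are taken from headers up to
#' the first whitespace, sequences are case-folded and T is normalized to U.
#' With `aligned = TRUE` the file is interpreted as a gapped alignment
#' (`-` for gaps) and all rows must have equal length.
#'
#' @param path Path to an existing, non-empty FASTA file.
#' @param aligned Interpret the file as a gapped alignment?
#' @return A list of [target_seq()] objects, or an [alignment()] when
#'   `aligned = TRUE`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGUACGU", ">b", "GGGCCCAA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup),
                                                       collapse = ", "))
  seqs <- unname(as.character(set))
  if (aligned) {
    return(alignment(ids, seqs))
  }
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("gapped sequences found; use aligned = TRUE for alignment input")
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- tryCatch(target_seq(ids[i], seqs[i]),
                         error = function(e) {
                           stop(sprintf("record '%s': %s", ids[i],
                                        conditionMessage(e)), call. = FALSE)
                         })
  }
  names(out) <- ids
  out
}

#' Write targets or an alignment to FASTA
#'
#' @param x A list of [target_seq()] objects or an [alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "alignment")) {
    set <- Biostrings::BStringSet(stats::setNames(x$rows, x$ids))
  } else {
    if (inherits(x, "target_seq")) x <- list(x)
    set <- Biostrings::BStringSet(
      stats::setNames(vapply(x, `[[`, character(1L), "seq"),
                      vapply(x, `[[`, character(1L), "id")))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Collect the tiling results inside a design (single tiling or shared
# design) as a named list.
design_tilings <- function(design) {
  if (inherits(design, "tiling_result")) {
    out <- list(design)
    names(out) <- design$target_id
    out
  } else if (inherits(design, "shared_design")) {
    design$per_target
  } else {
    stop("expected a tiling_result or shared_design")
  }
}

#' Flatten a design into the canonical oligo table
#'
#' One row per placed oligo with 1-based inclusive coordinates (ordering-
#' sheet friendly; the BED writer uses 0-based half-open), Tm rounded to two
#' decimals for display, and the untiled gap to the previous oligo (the 5'
#' end counts as a virtual previous oligo).
#'
#' @param design A `tiling_result` or `shared_design`.
#' @return A data.frame with columns `oligo_id`, `target_id`, `start_1based`,
#'   `end_1based`, `length`, `antisense_seq`, `tm_c`, `oligo_class`,
#'   `n_expansions`, `gap_to_previous`.
#' @export
oligo_table <- function(design) {
  tilings <- design_tilings(design)
  rows <- lapply(tilings, function(tr) {
    ol <- tr$oligos
    if (nrow(ol) == 0L) return(NULL)
    prev_end <- c(0L, ol$end[-nrow(ol)])
    data.frame(oligo_id = ol$id,
               target_id = ol$target_id,
               start_1based = ol$start + 1L,
               end_1based = ol$end,
               length = ol$end - ol$start,
               antisense_seq = ol$antisense_seq,
               tm_c = round(ol$tm, 2),
               oligo_class = ol$oligo_class,
               n_expansions = ol$n_expansions,
               gap_to_previous = ol$start - prev_end,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(oligo_id = character(), target_id = character(),
                      start_1based = integer(), end_1based = integer(),
                      length = integer(), antisense_seq = character(),
                      tm_c = numeric(), oligo_class = character(),
                      n_expansions = integer(), gap_to_previous = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the oligo table as TSV
#'
#' Tab-separated, header line, UTF-8, `\n` line endings, columns in the
#' exact order of [oligo_table()]. Coordinates are 1-based inclusive.
#'
#' @param design A `tiling_result` or `shared_design` (or a data.frame
#'   already in [oligo_table()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligo_table <- function(design, path) {
  tab <- if (is.data.frame(design)) design else oligo_table(design)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an oligo table written by [write_oligo_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame in [oligo_table()] layout.
#' @export
read_oligo_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(oligo_id = "character",
                                          target_id = "character",
                                          antisense_seq = "character",
                                          oligo_class = "character"))
  need <- c("oligo_id", "target_id", "start_1based", "end_1based", "length",
            "antisense_seq", "tm_c", "oligo_class", "n_expansions",
            "gap_to_previous")
  if (!identical(names(tab), need)) {
    stop("unexpected oligo table columns in ", path)
  }
  tab
}

#' Write oligo footprints as BED6
#'
#' Standard BED: 0-based half-open coordinates on the target, name is the
#' oligo id, score is the rounded Tm, strand is `-` (oligos are antisense to
#' the target's sense orientation).
#'
#' @param design A `tiling_result` or `shared_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(design, path) {
  tab <- oligo_table(design)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t-",
                   tab$target_id, tab$start_1based - 1L, tab$end_1based,
                   tab$oligo_id, as.integer(round(tab$tm_c)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
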