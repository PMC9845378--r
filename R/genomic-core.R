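#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#'   findOverlaps countOverlaps reduce resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

# All files are BED-family: 0-based, half-open. In memory every region is a
# GRanges (1-based, closed); the conversion happens only in read_bed/write_bed
# and read_bedpe, so overlap arithmetic everywhere else is format-agnostic.

#' Deterministic sort order for genomic intervals
#'
#' Orders by chromosome (lexicographic), start, end, then name if present.
#' Used everywhere an output must be reproducible down to row order.
#'
#' @param gr A `GRanges`.
#' @return An integer permutation of `seq_along(gr)`.
#' @export
interval_order <- function(gr) {
  nm <- if (!is.null(names(gr))) names(gr) else rep("", length(gr))
  order(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr), nm,
        method = "radix")
}

#' Sort intervals into the package's canonical order
#'
#' @param gr A `GRanges`.
#' @return The same `GRanges`, reordered by [interval_order()].
#' @export
sort_intervals <- function(gr) gr[interval_order(gr)]

#' Interval midpoint
#'
#' Midpoint base used for promoter distance, motif pair distance and
#' nearest-TSS assignment: `floor((start + end) / 2)` on internal 1-based
#' closed coordinates, so a width-1 interval is its own midpoint.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of midpoint positions.
#' @export
interval_midpoint <- function(gr) {
  as.integer(floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2))
}

# key identifying a region up to exact coordinates (strand ignored: the screen
# readout is strandless)
.coord_key <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr), sep = ":")
}

.skip_bed_line <- function(x) {
  grepl("^(#|track\\b|browser\\b)", x) | !nzchar(trimws(x))
}

#' Read a BED file into a GRanges
#'
#' Accepts BED3/BED6 with optional extra columns. Coordinates are interpreted
#' 0-based half-open and converted to 1-based closed. `track`, `browser`,
#' comment and blank lines are skipped. Malformed lines (non-integer
#' coordinates, `end <= start`, negative start, fewer than 3 columns) raise an
#' error naming the offending line number.
#'
#' @param path Path to a tab-separated BED file.
#' @param summit If `TRUE`, column 7 is read as a 0-based summit offset from
#'   the interval start and stored as absolute position in `mcols()$summit`.
#' @return A `GRanges`, one range per data line in file order, with `name`,
#'   `score`, strand and optionally `summit` metadata when present.
#' @export
read_bed <- function(path, summit = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !.skip_bed_line(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED parse error at line ", lineno[which(ncol < 3L)[1]],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | s < 0L | e <= s | !nzchar(chrom)
  if (any(bad)) {
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": invalid coordinates (need integer start >= 0, end > start)")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e))
  if (all(ncol >= 4L)) names(gr) <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5L)) {
    GenomicRanges::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(ncol >= 6L)) {
    str <- vapply(fields, `[[`, "", 6L)
    str[!str %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- str
  }
  if (summit) {
    if (!all(ncol >= 7L)) stop("summit = TRUE requires a 7th column")
    off <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 7L)))
    if (any(is.na(off))) {
      stop("BED parse error at line ", lineno[which(is.na(off))[1]],
           ": non-integer summit offset")
    }
    GenomicRanges::mcols(gr)$summit <- s + off + 1L
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Inverse of [read_bed()]: coordinates are converted back to 0-based
#' half-open. `name`, `score`, strand and `summit` are emitted when present so
#' that `read_bed(write_bed(x))` round-trips coordinates exactly.
#'
#' @param gr A `GRanges`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr))
  has_summit <- "summit" %in% colnames(GenomicRanges::mcols(gr))
  has_score <- "score" %in% colnames(GenomicRanges::mcols(gr))
  need6 <- has_summit
  if (!is.null(names(gr)) || has_score || need6) {
    cols <- c(cols, list(if (!is.null(names(gr))) names(gr) else "."))
  }
  if (has_score || need6) {
    sc <- if (has_score) GenomicRanges::mcols(gr)$score else 0
    cols <- c(cols, list(sc))
  }
  if (length(cols) >= 5L || need6) {
    cols <- c(cols, list(as.character(GenomicRanges::strand(gr))))
  }
  if (has_summit) {
    cols <- c(cols, list(GenomicRanges::mcols(gr)$summit -
                           GenomicRanges::start(gr)))
  }
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of aligned read pairs
#'
#' Accepts the minimal 6-column dialect (`chrom1 start1 end1 chrom2 start2
#' end2`) or the 10-column dialect (adding `name score strand1 strand2`).
#' Parsing does not filter: inter-chromosomal pairs are retained and handled
#' downstream by [pairs_to_fragments()]. `mapq` is `NA` ("pre-filtered
#' upstream") unless an 11th column supplies it.
#'
#' @param path Path to a tab-separated BEDPE file.
#' @return A data frame with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   (1-based closed), plus `name`, `mapq`. Zero rows for an empty file.
#' @export
read_bedpe <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !.skip_bed_line(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character(), mapq = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  ok <- ncol == 6L | ncol >= 10L
  if (!all(ok)) {
    stop("BEDPE parse error at line ", lineno[which(!ok)[1]],
         ": expected 6 or >=10 columns, got ", ncol[which(!ok)[1]])
  }
  num <- function(i) suppressWarnings(as.integer(vapply(fields, `[[`, "", i)))
  chr <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(chrom1 = chr(1L), start1 = num(2L), end1 = num(3L),
                    chrom2 = chr(4L), start2 = num(5L), end2 = num(6L),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$start1) | is.na(out$end1) | is.na(out$start2) |
    is.na(out$end2) | out$end1 <= out$start1 | out$end2 <= out$start2 |
    out$start1 < 0L | out$start2 < 0L
  if (any(bad)) {
    stop("BEDPE parse error at line ", lineno[which(bad)[1]],
         ": invalid coordinates")
  }
  out$start1 <- out$start1 + 1L
  out$start2 <- out$start2 + 1L
  out$name <- if (all(ncol >= 7L)) chr(7L) else NA_character_
  out$mapq <- if (all(ncol >= 11L)) num(11L) else NA_integer_
  out
}

#' Reconstruct cloned fragments from read pairs
#'
#' Each properly mapped pair represents one cloned fragment spanning from the
#' outermost coordinate of one mate to the outermost coordinate of the other:
#' `min(start1, start2) .. max(end1, end2)`. Using min/max rather than the
#' literal mate order makes the reconstruction symmetric under mate swapping.
#' Pairs are dropped (and counted in the returned ledger, never silently) when
#' mates map to different chromosomes, when the implied span exceeds
#' `max_len`, or when a present mapq is not strictly above `mapq_min`.
#'
#' @param pairs Data frame from [read_bedpe()].
#' @param max_len Maximum fragment span in bp (default 600, the aligner's
#'   insert cap for a 350-650 bp size-selected library).
#' @param mapq_min Mapping-quality threshold; a pair is kept only if
#'   `mapq > mapq_min`. Pairs with `NA` mapq are treated as pre-filtered and
#'   kept.
#' @return A list with `fragments` (a `GRanges`) and `ledger`, a named integer
#'   vector with elements `input`, `retained`, `inter_chrom`, `too_long`,
#'   `low_mapq` satisfying `input = retained + drops`.
#' @export
pairs_to_fragments <- function(pairs, max_len = 600L, mapq_min = 40L) {
  n <- nrow(pairs)
  low_mapq <- !is.na(pairs$mapq) & pairs$mapq <= mapq_min
  inter <- !low_mapq & pairs$chrom1 != pairs$chrom2
  s <- pmin(pairs$start1, pairs$start2)
  e <- pmax(pairs$end1, pairs$end2)
  too_long <- !low_mapq & !inter & (e - s + 1L) > max_len
  keep <- !(low_mapq | inter | too_long)
  frags <- GenomicRanges::GRanges(pairs$chrom1[keep],
                                  IRanges::IRanges(s[keep], e[keep]))
  ledger <- c(input = n, retained = sum(keep),
              inter_chrom = sum(inter), too_long = sum(too_long),
              low_mapq = sum(low_mapq))
  list(fragments = frags, ledger = ledger)
}

#' Remove duplicate fragments
#'
#' Keeps exactly one copy of each distinct `(chrom, start, end)` tuple — the
#' screen treats each unique fragment as one unit of evidence, so PCR copies
#' must collapse. The survivor is the first occurrence in canonical sort
#' order, so metadata columns are preserved deterministically and the
#' operation is idempotent.
#'
#' @param gr A `GRanges`, possibly with metadata columns.
#' @return A sorted `GRanges` with duplicates removed.
#' @export
dedupe <- function(gr) {
  gr <- sort_intervals(gr)
  gr[!duplicated(.coord_key(gr))]
}

#' Label query intervals that overlap a subject set
#'
#' A query is labelled `TRUE` iff it shares at least `min_bp` bases with at
#' least one subject interval (half-open arithmetic: overlap length is
#' `max(0, min(ends) - max(starts))` in BED coordinates).
#'
#' @param query,subject `GRanges` objects.
#' @param min_bp Minimum shared bases (default 1); must be >= 1.
#' @return A data frame with one row per query: `hit` (logical) and
#'   `subject_index` (index of the first overlapping subject in input order,
#'   `NA` when none).
#' @export
overlap_any <- function(query, subject, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  ov <- GenomicRanges::findOverlaps(query, subject, minoverlap = min_bp)
  idx <- rep(NA_integer_, length(query))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  first <- !duplicated(qh)
  idx[qh[first]] <- sh[first]
  data.frame(hit = !is.na(idx), subject_index = idx)
}
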