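# Differential chromatin accessibility by plain fold threshold: union peaks,
# count tags in 400 bp summit-centred windows, CPM-normalize, log2(CPM + 1),
# average replicates after the transform, and call a site differential when
# the condition means differ by at least log2(fold).

#' Merge two summit-carrying peak sets into a union
#'
#' Overlapping peaks are merged to their union span; the merged summit is the
#' summit of the higher input peak (height ties broken towards the leftmost
#' peak, then the leftmost summit).
#'
#' @param peaks_a,peaks_b `GRanges` with `summit` (absolute position) and
#'   `height` metadata columns.
#' @return A union `GRanges` with `summit` and `height` metadata.
#' @export
peak_union <- function(peaks_a, peaks_b) {
  pk <- c(peaks_a, peaks_b)
  smt <- GenomicRanges::mcols(pk)$summit
  hgt <- GenomicRanges::mcols(pk)$height
  if (is.null(smt) || is.null(hgt)) {
    stop("peaks need summit and height metadata columns")
  }
  if (any(smt < GenomicRanges::start(pk) | smt > GenomicRanges::end(pk))) {
    stop("summit outside its peak interval")
  }
  red <- GenomicRanges::reduce(sort_intervals(pk), with.revmap = TRUE)
  rev <- GenomicRanges::mcols(red)$revmap
  pick <- vapply(rev, function(ii) {
    best <- ii[hgt[ii] == max(hgt[ii])]
    best <- best[GenomicRanges::start(pk)[best] ==
                   min(GenomicRanges::start(pk)[best])]
    best[which.min(smt[best])]
  }, integer(1))
  out <- GenomicRanges::granges(red)
  GenomicRanges::mcols(out)$summit <- smt[pick]
  GenomicRanges::mcols(out)$height <- hgt[pick]
  out
}

#' Count tags in fixed windows centred on peak summits
#'
#' The window is half-open `[summit - width/2, summit + width/2)` in BED
#' coordinates; a tag/fragment is counted when it overlaps the window by at
#' least one base. Windows running off a chromosome end are clipped and
#' flagged, not dropped.
#'
#' @param union A `GRanges` with a `summit` metadata column.
#' @param tags Either a `GRanges` (one sample) or a named list of `GRanges`
#'   (one element per sample).
#' @param width Window width in bp; must be even.
#' @param chrom_len Optional named vector of chromosome lengths for clipping.
#' @return A list with `counts` (matrix sites x samples) and `clipped`
#'   (logical per site).
#' @export
window_counts <- function(union, tags, width = 400L, chrom_len = NULL) {
  if (width %% 2L != 0L) stop("window width must be even")
  smt <- GenomicRanges::mcols(union)$summit
  if (is.null(smt)) stop("union peaks need a summit metadata column")
  half <- width %/% 2L
  s <- smt - half
  e <- smt + half - 1L
  clipped <- s < 1L
  s <- pmax(s, 1L)
  if (!is.null(chrom_len)) {
    lim <- chrom_len[as.character(GenomicRanges::seqnames(union))]
    clipped <- clipped | e > lim
    e <- pmin(e, lim)
  }
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(union),
                                IRanges::IRanges(s, e))
  if (!is.list(tags)) tags <- list(sample = tags)
  counts <- vapply(tags, function(t) GenomicRanges::countOverlaps(win, t),
                   integer(length(win)))
  counts <- matrix(counts, nrow = length(win),
                   dimnames = list(names(union), names(tags)))
  list(counts = counts, clipped = clipped)
}

#' CPM-normalize, log-transform and average replicates
#'
#' Per sample column: `CPM = 1e6 * count / column total`, then
#' `log2(CPM + 1)`; replicate columns of a condition are averaged after the
#' transform.
#'
#' @param counts Non-negative matrix, sites x samples.
#' @param condition Character vector, one condition label per column.
#' @return A list with `norm` (log2(CPM+1) per sample) and `means`
#'   (sites x conditions, replicate-averaged).
#' @export
normalize_counts <- function(counts, condition) {
  stopifnot(ncol(counts) == length(condition))
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every sample column must have a positive total")
  cpm <- sweep(counts, 2L, tot, "/") * 1e6
  norm <- log2(cpm + 1)
  conds <- unique(condition)
  means <- vapply(conds, function(cd) {
    rowMeans(norm[, condition == cd, drop = FALSE])
  }, numeric(nrow(counts)))
  means <- matrix(means, nrow = nrow(counts),
                  dimnames = list(rownames(counts), conds))
  list(norm = norm, means = means)
}

#' Fold-threshold differential accessibility calls
#'
#' Default method `"log_difference"`: a site is `gained` iff
#' `mean_a - mean_b >= log2(fold)` on the log2(CPM+1) scale, `lost` iff
#' `<= -log2(fold)`, otherwise `unchanged`. Method `"cpm_ratio"` applies the
#' fold threshold to the ratio of back-transformed CPM values instead.
#'
#' @param mean_a,mean_b Per-condition mean columns (same site universe).
#' @param fold Fold-change threshold (> 1); default 2.
#' @param method `"log_difference"` (default) or `"cpm_ratio"`.
#' @return Character vector per site: `"gained"`, `"lost"` or `"unchanged"`
#'   (gained = higher in `a`).
#' @export
call_differential <- function(mean_a, mean_b, fold = 2,
                              method = c("log_difference", "cpm_ratio")) {
  if (fold <= 1) stop("fold threshold must be > 1")
  method <- match.arg(method)
  stopifnot(length(mean_a) == length(mean_b))
  if (method == "log_difference") {
    d <- mean_a - mean_b
    thr <- log2(fold)
    ifelse(d >= thr, "gained", ifelse(d <= -thr, "lost", "unchanged"))
  } else {
    ra <- 2^mean_a - 1
    rb <- 2^mean_b - 1
    gained <- ra >= fold * rb & ra > 0
    lost <- rb >= fold * ra & rb > 0
    ifelse(gained & !lost, "gained", ifelse(lost & !gained, "lost",
                                            "unchanged"))
  }
}
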