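# Motif-pair co-localization statistics.
#
# Observed pair counts x: among motif hits lying in a region set, every
# unordered pair of distinct hit instances whose midpoints are within
# `window` bp increments the (motif_a, motif_b) cell; coordinate-identical
# hit intervals (100% mutual overlap, degenerate matches from overlapping
# motif definitions) are excluded. Homotypic pairs fall on the diagonal as
# C(k, 2) instance pairs per clique. The null is built by repeatedly drawing
# the same number of sites uniformly without replacement from the universe of
# all distal sites and recounting; z = (x - mu) / sigma per pair.

.pair_candidates <- function(hits, window, anchor) {
  # all candidate hit pairs genome-wide, before any region restriction
  motif_names <- names(hits)
  gr <- do.call(c, lapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    GenomicRanges::mcols(h) <- NULL
    names(h) <- NULL
    h
  }))
  motif <- rep(seq_along(hits), lengths(hits))
  if (length(gr) == 0L) {
    return(list(gr = gr, motif = motif, i = integer(0), j = integer(0),
                names = motif_names))
  }
  if (anchor == "center") {
    mid <- interval_midpoint(gr)
    pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(mid, mid))
    ov <- GenomicRanges::findOverlaps(pts, maxgap = window - 1L,
                                      drop.self = TRUE, drop.redundant = TRUE)
  } else {
    ov <- GenomicRanges::findOverlaps(gr, maxgap = window,
                                      drop.self = TRUE, drop.redundant = TRUE)
  }
  i <- S4Vectors::queryHits(ov)
  j <- S4Vectors::subjectHits(ov)
  # exclude coordinate-identical hit intervals (100% mutual overlap)
  key <- .coord_key(gr)
  keep <- key[i] != key[j]
  list(gr = gr, motif = motif, i = i[keep], j = j[keep], names = motif_names)
}

.pair_matrix <- function(pc, keep_pair) {
  nm <- length(pc$names)
  x <- matrix(0L, nm, nm, dimnames = list(pc$names, pc$names))
  if (any(keep_pair)) {
    a <- pmin(pc$motif[pc$i[keep_pair]], pc$motif[pc$j[keep_pair]])
    b <- pmax(pc$motif[pc$i[keep_pair]], pc$motif[pc$j[keep_pair]])
    tab <- table(factor(a, levels = seq_len(nm)),
                 factor(b, levels = seq_len(nm)))
    x <- x + matrix(as.integer(tab), nm, nm,
                    dimnames = list(pc$names, pc$names))
    x <- x + t(x * upper.tri(x))
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
  }
  x
}

#' Count co-localized motif pairs within a region set
#'
#' Only hits overlapping the region set (>= 1 bp) are considered. For each
#' unordered pair of distinct hit instances with midpoints at most `window`
#' bp apart (inclusive, center-to-center; `anchor = "edge"` switches to
#' edge-to-edge gap), the corresponding motif-pair cell is incremented,
#' except pairs of coordinate-identical intervals. The diagonal holds
#' homotypic counts: a clique of k same-motif hits contributes C(k, 2).
#'
#' @param hits Named list of `GRanges`, one element per motif.
#' @param regions A `GRanges` region set.
#' @param window Distance cutoff in bp (> 0).
#' @param anchor `"center"` (default) or `"edge"`.
#' @return A symmetric integer matrix over motif names with attribute
#'   `n_regions`.
#' @export
count_motif_pairs <- function(hits, regions, window = 50L,
                              anchor = c("center", "edge")) {
  anchor <- match.arg(anchor)
  if (window <= 0L) stop("window must be > 0")
  stopifnot(is.list(hits), !is.null(names(hits)))
  pc <- .pair_candidates(hits, window, anchor)
  if (length(pc$gr) == 0L) {
    x <- matrix(0L, length(hits), length(hits),
                dimnames = list(names(hits), names(hits)))
    attr(x, "n_regions") <- length(regions)
    return(x)
  }
  in_reg <- GenomicRanges::countOverlaps(pc$gr, regions) > 0L
  keep <- in_reg[pc$i] & in_reg[pc$j]
  x <- .pair_matrix(pc, keep)
  attr(x, "n_regions") <- length(regions)
  x
}

# Precomputed pair table against a fixed site universe: the hit-to-site
# overlap map is stored once, so membership of a sampled site subset can be
# evaluated per repetition without re-running the overlap engine.
.pair_index <- function(hits, universe, window = 50L,
                        anchor = c("center", "edge")) {
  anchor <- match.arg(anchor)
  pc <- .pair_candidates(hits, window, anchor)
  qh <- integer(0); sh <- integer(0)
  if (length(pc$gr) > 0L) {
    ov <- GenomicRanges::findOverlaps(pc$gr, universe)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
  }
  list(pc = pc, hit_of = qh, site_of = sh,
       n_hits = length(pc$gr), n_universe = length(universe))
}

.count_from_index <- function(idx, member) {
  # member: logical over universe sites; a hit counts when it overlaps any
  # retained site, a pair when both hits count
  hit_ok <- rep(FALSE, idx$n_hits)
  hit_ok[idx$hit_of[member[idx$site_of]]] <- TRUE
  keep <- hit_ok[idx$pc$i] & hit_ok[idx$pc$j]
  .pair_matrix(idx$pc, keep)
}

#' Resampled null distribution of motif-pair counts
#'
#' For each of `reps` repetitions, `n_draw` sites are sampled uniformly
#' without replacement from the universe of sites, pairs are counted on the
#' sampled set exactly as in [count_motif_pairs()], and the per-pair mean and
#' sample standard deviation (divisor `reps - 1`) over repetitions are
#' returned. One seeded generator drives the whole run, so results are
#' reproducible.
#'
#' @param hits Named list of `GRanges`, one per motif.
#' @param universe A `GRanges` of all candidate sites (e.g. all distal sites
#'   of a stage).
#' @param n_draw Sites per draw; must not exceed the universe size.
#' @param reps Number of repetitions (>= 2); default 1000.
#' @param window,anchor Passed to the pair counter.
#' @param seed Optional integer seed.
#' @return A list of class `pair_null` with `mu`, `sigma` (matrices), `reps`,
#'   `n_draw`, `seed`.
#' @export
resample_null <- function(hits, universe, n_draw, reps = 1000L,
                          window = 50L, anchor = c("center", "edge"),
                          seed = NULL) {
  anchor <- match.arg(anchor)
  if (reps < 2L) stop("reps must be >= 2")
  if (n_draw > length(universe)) {
    stop("n_draw exceeds the size of the site universe")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- .pair_index(hits, universe, window, anchor)
  nm <- length(hits)
  sum1 <- matrix(0, nm, nm, dimnames = list(names(hits), names(hits)))
  sum2 <- sum1
  for (r in seq_len(reps)) {
    member <- rep(FALSE, idx$n_universe)
    member[sample.int(idx$n_universe, n_draw)] <- TRUE
    x <- .count_from_index(idx, member)
    sum1 <- sum1 + x
    sum2 <- sum2 + x^2
  }
  mu <- sum1 / reps
  sigma <- sqrt(pmax((sum2 - reps * mu^2) / (reps - 1), 0))
  structure(list(mu = mu, sigma = sigma, reps = reps, n_draw = n_draw,
                 seed = seed, window = window, anchor = anchor),
            class = "pair_null")
}

#' Motif-pair co-localization z-scores
#'
#' `z = (x - mu) / sigma` per motif pair. A positive z means the pair is
#' co-localized in the specific set more often than expected from random
#' draws of the same number of sites. When `sigma = 0`, z is 0 if `x = mu`
#' and `+/- cap` otherwise, flagged in `capped`.
#'
#' @param x Observed pair-count matrix from [count_motif_pairs()].
#' @param null A `pair_null` from [resample_null()].
#' @param cap Magnitude assigned to zero-variance disagreements.
#' @return A list with `z` (matrix) and `capped` (logical matrix).
#' @export
pair_zscore <- function(x, null, cap = 10) {
  if (!identical(dimnames(x)[[1]], dimnames(null$mu)[[1]])) {
    stop("pair universes of x and the null do not match")
  }
  z <- (x - null$mu) / null$sigma
  capped <- null$sigma == 0 & x != null$mu
  z[null$sigma == 0] <- 0
  z[capped] <- sign(x - null$mu)[capped] * cap
  list(z = z, capped = capped)
}

#' Relative motif enrichment score across peak sets
#'
#' For motif i and peak set j, `S_ij = (n_ij / m_j) / (sum_j n_ij /
#' sum_j m_j)`: the per-set motif rate divided by the pooled rate across all
#' sets. Defined rows satisfy the weighted-mean identity
#' `sum_j (m_j / sum m) * S_ij = 1`. Motifs with zero instances everywhere
#' are flagged undefined (`NA` row).
#'
#' @param n Matrix of motif instance counts, motifs x peak sets.
#' @param m Vector of peak-set sizes (all > 0), one per column of `n`.
#' @return A list with `S` (matrix), `undefined` (logical per motif), and
#'   the inputs `n`, `m`.
#' @export
relative_enrichment <- function(n, m) {
  stopifnot(ncol(n) == length(m))
  if (any(m <= 0)) stop("every peak-set size m_j must be > 0")
  pooled <- rowSums(n) / sum(m)
  rate <- sweep(n, 2L, m, "/")
  S <- sweep(rate, 1L, pooled, "/")
  undefined <- rowSums(n) == 0
  S[undefined, ] <- NA_real_
  list(S = S, undefined = undefined, n = n, m = m)
}

#' Z-scale a matrix by rows or columns
#'
#' Each vector along the chosen axis is transformed to mean 0, sd 1 (sample
#' sd). Constant vectors become all zero and are flagged.
#'
#' @param mat A numeric matrix.
#' @param axis `"column"` (default, as in column-scaled heatmaps) or
#'   `"row"`.
#' @return A list with `scaled` (matrix) and `constant` (logical per scaled
#'   vector).
#' @export
zscale <- function(mat, axis = c("column", "row")) {
  axis <- match.arg(axis)
  if (axis == "row") {
    out <- zscale(t(mat), axis = "column")
    return(list(scaled = t(out$scaled), constant = out$constant))
  }
  if (nrow(mat) < 2L) stop("need >= 2 entries along the scaled axis")
  mu <- colMeans(mat)
  sd <- apply(mat, 2L, stats::sd)
  constant <- sd == 0
  sd[constant] <- 1
  scaled <- sweep(sweep(mat, 2L, mu, "-"), 2L, sd, "/")
  scaled[, constant] <- 0
  list(scaled = scaled, constant = constant)
}

#' Complete-linkage leaf ordering for heatmap display
#'
#' Agglomerative complete-linkage clustering of the rows on Euclidean
#' distance, as used to order motif matrices for display. Undefined entries
#' must be filtered or imputed first.
#'
#' @param mat A numeric matrix with >= 2 rows and no `NA`/`NaN` entries.
#' @return A list with `order` (leaf permutation), `merge` and `height` (the
#'   agglomeration tree, `stats::hclust` encoding).
#' @export
hcluster_order <- function(mat) {
  if (anyNA(mat)) {
    stop("matrix contains undefined entries; filter or flag them first")
  }
  if (nrow(mat) < 2L) stop("need >= 2 rows to cluster")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  list(order = hc$order, merge = hc$merge, height = hc$height)
}
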