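# Independent brute-force oracles, deliberately written against plain
# coordinate arithmetic (no IRanges machinery) so they stay independent of
# the code paths they check.

library(GenomicRanges)

# build a GRanges from BED (0-based half-open) coordinates
bed_gr <- function(chrom, start, end, ...) {
  chrom <- rep(chrom, length.out = length(start))
  gr <- GRanges(chrom, IRanges::IRanges(start + 1L, end))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

gr_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             stringsAsFactors = FALSE)
}

# O(n^2) overlap labels: >= min_bp shared bases, half-open arithmetic on BED
# coordinates
brute_overlap <- function(query, subject, min_bp = 1L) {
  q <- gr_df(query); s <- gr_df(subject)
  vapply(seq_len(nrow(q)), function(i) {
    same <- s$chrom == q$chrom[i]
    if (!any(same)) return(FALSE)
    ov <- pmin(s$end[same], q$end[i]) - pmax(s$start[same], q$start[i]) + 1L
    any(ov >= min_bp)
  }, logical(1))
}

# O(n^2) motif pair enumeration: hits kept iff they overlap the region set,
# pairs counted iff midpoints within `window` and coordinates not identical
brute_pair_count <- function(hits, regions, window) {
  nm <- names(hits)
  df <- do.call(rbind, lapply(seq_along(hits), function(m) {
    d <- gr_df(hits[[m]]); if (nrow(d)) d$motif <- m; d
  }))
  x <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  if (is.null(df) || nrow(df) == 0L) return(x)
  keep <- brute_overlap(bed_gr(df$chrom, df$start - 1L, df$end), regions)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) return(x)
  mid <- floor((df$start + df$end) / 2)
  for (i in seq_len(nrow(df) - 1L)) {
    for (j in (i + 1L):nrow(df)) {
      if (df$chrom[i] != df$chrom[j]) next
      if (abs(mid[i] - mid[j]) > window) next
      if (df$start[i] == df$start[j] && df$end[i] == df$end[j]) next
      a <- min(df$motif[i], df$motif[j]); b <- max(df$motif[i], df$motif[j])
      x[a, b] <- x[a, b] + 1L
      if (a != b) x[b, a] <- x[b, a] + 1L
    }
  }
  x
}

# exhaustive nearest-TSS scan with the same tie-break rule (smaller TSS
# coordinate, then lexicographically smaller gene id; Inf across chromosomes)
brute_nearest <- function(enhancers, tss) {
  e <- gr_df(enhancers)
  mid <- floor((e$start + e$end) / 2)
  tp <- start(tss); tc <- as.character(seqnames(tss))
  gid <- mcols(tss)$gene_id
  out_g <- character(nrow(e)); out_d <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    d <- ifelse(tc == e$chrom[i], abs(mid[i] - tp), Inf)
    ord <- order(d, tp, gid)
    out_g[i] <- gid[ord[1L]]
    out_d[i] <- d[ord[1L]]
  }
  data.frame(gene_id = out_g, distance = out_d, stringsAsFactors = FALSE)
}

# per-base window counting: a fragment counts when any of its bases falls in
# the window (internal closed coordinates)
brute_window_count <- function(win, frags) {
  w <- gr_df(win); f <- gr_df(frags)
  vapply(seq_len(nrow(w)), function(i) {
    sum(f$chrom == w$chrom[i] & f$start <= w$end[i] & f$end >= w$start[i])
  }, numeric(1))
}

# tiny agglomerative complete-linkage on Euclidean distance, returning merge
# heights in agglomeration order
brute_complete_linkage_heights <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# small simulated screen shared by several tests
small_sim <- function(seed = 101, n_genes = 80, ...) {
  simulate_screen(sim_config(seed = seed, n_sites_per_stage = 150,
                             n_genes = n_genes, ...))
}
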