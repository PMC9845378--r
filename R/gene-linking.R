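# Enhancer-to-gene assignment: the union of chromatin-interaction anchor
# pairs links an enhancer to a gene whenever the enhancer overlaps one anchor
# and the gene's promoter window overlaps the other; enhancers left unlinked
# fall back to the nearest TSS. Linked activity patterns are joined with a
# gene-by-stage expression table, and the responsive-enhancer to
# responsive-gene linkage fraction summarises how often accessibility
# responses propagate to expression.

# midpoint-to-TSS distance (Inf across chromosomes) with deterministic
# tie-breaking: smaller TSS coordinate, then lexicographic gene id
.nearest_tss_distance <- function(x, tss) {
  xm <- interval_midpoint(x)
  xc <- as.character(GenomicRanges::seqnames(x))
  tp <- GenomicRanges::start(tss)
  tc <- as.character(GenomicRanges::seqnames(tss))
  gid <- GenomicRanges::mcols(tss)$gene_id
  if (is.null(gid)) gid <- if (!is.null(names(tss))) names(tss)
    else as.character(seq_along(tss))
  # candidate order encodes the tie-break: distance, then coordinate, then id
  ord <- order(tp, gid, method = "radix")
  best_d <- rep(Inf, length(x))
  best_i <- rep(NA_integer_, length(x))
  for (ch in unique(tc)) {
    ti <- ord[tc[ord] == ch]
    if (length(ti) == 0L) next
    qi <- which(xc == ch)
    if (length(qi) == 0L) next
    pos <- tp[ti]
    # pos is sorted; scan the insertion neighbourhood of each query midpoint
    lo <- findInterval(xm[qi], pos)
    for (k in seq_along(qi)) {
      cand <- unique(pmin(pmax(c(lo[k], lo[k] + 1L), 1L), length(pos)))
      d <- abs(xm[qi[k]] - pos[cand])
      # on distance ties, candidates are already in tie-break order
      w <- cand[which.min(d)]
      best_d[qi[k]] <- min(d)
      best_i[qi[k]] <- ti[w]
    }
  }
  # intervals on chromosomes without a TSS: fall back to the global
  # tie-break order with infinite distance, so every element still links
  missing <- is.na(best_i)
  if (any(missing) && length(tss) > 0L) best_i[missing] <- ord[1L]
  list(distance = best_d, index = best_i,
       gene_id = gid[best_i])
}

#' Promoter windows around TSS
#'
#' TSS +/- `flank` bp, the same promoter definition used by the fragment
#' classifier, reused for matching interaction anchors to promoters.
#'
#' @param tss A width-1 `GRanges` with `gene_id` metadata (or names).
#' @param flank Flank size in bp (default 1500).
#' @return A `GRanges` of promoter windows with `gene_id` metadata.
#' @export
promoter_windows <- function(tss, flank = 1500L) {
  gid <- GenomicRanges::mcols(tss)$gene_id
  if (is.null(gid)) gid <- names(tss)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tss) - flank),
                     GenomicRanges::start(tss) + flank))
  GenomicRanges::mcols(out)$gene_id <- gid
  out
}

#' Link enhancers to genes through interaction anchor pairs
#'
#' An enhancer is linked to gene G iff it overlaps one anchor of an
#' interaction (>= 1 bp) and G's promoter window overlaps the other anchor,
#' for any interaction in the union; both anchor orientations are tried, so
#' the linking is symmetric in anchor order. Multiple links per enhancer are
#' kept.
#'
#' @param enhancers A `GRanges` named by site id.
#' @param interactions A list with parallel `GRanges` elements `anchor1` and
#'   `anchor2` (one interaction per position).
#' @param promoters Promoter windows from [promoter_windows()].
#' @return A list with `links` (data frame `site_id`, `gene_id`, `method`,
#'   `distance`) and `unlinked` (site ids with no interaction link).
#' @export
link_by_interactions <- function(enhancers, interactions, promoters) {
  ids <- if (!is.null(names(enhancers))) names(enhancers)
    else sprintf("site%05d", seq_along(enhancers))
  gid <- GenomicRanges::mcols(promoters)$gene_id
  one_way <- function(a1, a2) {
    # suppressed warning: disjoint seqlevels simply mean zero overlap here
    e_ov <- suppressWarnings(GenomicRanges::findOverlaps(enhancers, a1))
    p_ov <- suppressWarnings(GenomicRanges::findOverlaps(promoters, a2))
    # join on the interaction index
    em <- split(S4Vectors::queryHits(e_ov), S4Vectors::subjectHits(e_ov))
    pm <- split(S4Vectors::queryHits(p_ov), S4Vectors::subjectHits(p_ov))
    common <- intersect(names(em), names(pm))
    if (length(common) == 0L) {
      return(data.frame(site_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(common, function(ix) {
      expand.grid(site_id = ids[em[[ix]]], gene_id = gid[pm[[ix]]],
                  stringsAsFactors = FALSE)
    }))
  }
  links <- rbind(one_way(interactions$anchor1, interactions$anchor2),
                 one_way(interactions$anchor2, interactions$anchor1))
  links <- unique(links)
  if (nrow(links) > 0L) {
    links$method <- "interaction"
    links$distance <- NA_real_
    links <- links[order(links$site_id, links$gene_id), ]
    rownames(links) <- NULL
  } else {
    links <- data.frame(site_id = character(), gene_id = character(),
                        method = character(), distance = numeric(),
                        stringsAsFactors = FALSE)
  }
  list(links = links, unlinked = setdiff(ids, links$site_id))
}

#' Nearest-TSS fallback links
#'
#' Each enhancer is linked to the gene whose TSS minimizes the
#' midpoint-to-TSS distance; ties break to the smaller TSS coordinate, then
#' the lexicographically smaller gene id. Enhancers on a chromosome without
#' any TSS link to the first gene in tie-break order with infinite recorded
#' distance, so every enhancer ends up linked.
#'
#' @param enhancers A `GRanges` named by site id.
#' @param tss A non-empty width-1 `GRanges` with `gene_id` metadata.
#' @return A data frame `site_id`, `gene_id`, `method = "nearest"`,
#'   `distance`.
#' @export
nearest_gene <- function(enhancers, tss) {
  if (length(tss) == 0L) stop("TSS set must be non-empty")
  if (length(enhancers) == 0L) {
    return(data.frame(site_id = character(), gene_id = character(),
                      method = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  nn <- .nearest_tss_distance(enhancers, tss)
  data.frame(
    site_id = if (!is.null(names(enhancers))) names(enhancers)
      else sprintf("site%05d", seq_along(enhancers)),
    gene_id = nn$gene_id,
    method = "nearest",
    distance = nn$distance,
    stringsAsFactors = FALSE
  )
}

#' Link all enhancers: interactions first, nearest-TSS fallback
#'
#' @param enhancers A `GRanges` named by site id.
#' @param interactions As in [link_by_interactions()]; may be `NULL` to use
#'   the fallback only.
#' @param tss A width-1 `GRanges` with `gene_id` metadata.
#' @param flank Promoter window flank for anchor matching (bp).
#' @return A links data frame; every enhancer has >= 1 link, with `method`
#'   recording its provenance.
#' @export
link_enhancers <- function(enhancers, interactions, tss, flank = 1500L) {
  if (!is.null(interactions)) {
    ix <- link_by_interactions(enhancers, interactions,
                               promoter_windows(tss, flank))
    rest <- enhancers[names(enhancers) %in% ix$unlinked]
    near <- if (length(rest)) nearest_gene(rest, tss) else NULL
    out <- rbind(ix$links, near)
  } else {
    out <- nearest_gene(enhancers, tss)
  }
  rownames(out) <- NULL
  out
}

#' Join enhancer activity patterns with linked-gene expression
#'
#' One row per enhancer-gene link, grouped and sorted by the enhancer's
#' activity pattern code; expression columns are carried through
#' untransformed. Links to genes absent from the expression table are kept
#' and flagged, not dropped.
#'
#' @param activity Output of [binarize_activity()].
#' @param links Links data frame from [link_enhancers()].
#' @param expression Gene x stage expression matrix.
#' @return A data frame with `site_id`, `pattern`, `gene_id`, `method`, one
#'   expression column per stage, and `expr_missing`.
#' @export
activity_expression_table <- function(activity, links, expression) {
  df <- activity$matrix
  m <- match(links$site_id, df$site_id)
  out <- data.frame(site_id = links$site_id,
                    pattern = df$pattern[m],
                    gene_id = links$gene_id,
                    method = links$method,
                    stringsAsFactors = FALSE)
  em <- match(links$gene_id, rownames(expression))
  expr <- expression[ifelse(is.na(em), 1L, em), , drop = FALSE]
  expr[is.na(em), ] <- NA_real_
  out <- cbind(out, as.data.frame(expr, row.names = NULL))
  out$expr_missing <- is.na(em)
  out <- out[order(out$pattern, out$site_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of responsive enhancers linked to responsive genes
#'
#' `fraction = |responsive enhancers with >= 1 link to a responsive gene| /
#' |responsive enhancers with >= 1 link|` (any-link semantics: an enhancer
#' counts once however many links it has).
#'
#' @param responsive_enhancers Character vector of site ids.
#' @param links Links data frame.
#' @param responsive_genes Character vector of gene ids.
#' @return A list with `fraction` (`NA` when no responsive enhancer is
#'   linked) and `counts` (linked, linked_to_responsive, unlinked).
#' @export
responsive_linkage_fraction <- function(responsive_enhancers, links,
                                        responsive_genes) {
  sub <- links[links$site_id %in% responsive_enhancers, , drop = FALSE]
  linked <- unique(sub$site_id)
  hit <- unique(sub$site_id[sub$gene_id %in% responsive_genes])
  counts <- c(linked = length(linked),
              linked_to_responsive = length(hit),
              unlinked = length(setdiff(responsive_enhancers, linked)))
  fraction <- if (length(linked) == 0L) NA_real_
    else length(hit) / length(linked)
  list(fraction = fraction, counts = counts)
}
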