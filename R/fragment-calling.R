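# The calling pipeline: per stage and replicate, fragments are deduplicated,
# purged of PCR background artifacts (perfect-overlap match), restricted to
# that stage's open chromatin, and split into promoter/distal; any site with
# >= 1 overlapping positive-bin fragment in both replicates is called
# enhancer positive, and the per-stage consensus calls are binarized into a
# site-by-stage activity matrix with a pattern code per site.

.POSITIVE_BINS <- c("low", "medium", "high")
.YFP_BINS <- c("negative", "low", "medium", "high")

#' Remove fragments with a perfect background-library overlap
#'
#' A fragment is an artifact iff an identical `(chrom, start, end)` tuple
#' exists in the background library (the PCR product of untransfected DNA);
#' partial overlaps are retained — only exact coordinate matches are evidence
#' of a PCR artifact.
#'
#' @param fragments,background `GRanges`; both should be deduplicated.
#' @return A list with `fragments` (retained) and `removed` (count).
#' @export
remove_background <- function(fragments, background) {
  hit <- .coord_key(fragments) %in% .coord_key(background)
  list(fragments = fragments[!hit], removed = sum(hit))
}

#' Restrict fragments to a stage's open chromatin
#'
#' A fragment is retained iff it shares at least one base with at least one
#' open-chromatin site of its own differentiation stage. If both fragments
#' and sites carry a `stage` attribute they must agree.
#'
#' @param fragments A `GRanges`, optionally with a `stage` metadata column.
#' @param stage_sites A `GRanges` of that stage's sites.
#' @param stage Optional stage name to check fragment labels against.
#' @return A list with `fragments` (retained) and `removed` (count).
#' @export
restrict_to_open_chromatin <- function(fragments, stage_sites, stage = NULL) {
  fr_stage <- GenomicRanges::mcols(fragments)$stage
  if (!is.null(stage) && !is.null(fr_stage) && any(fr_stage != stage)) {
    stop("fragment stage labels do not match the supplied site set")
  }
  hit <- overlap_any(fragments, stage_sites)$hit
  list(fragments = fragments[hit], removed = sum(!hit))
}

#' Classify intervals as promoter-proximal or distal
#'
#' Promoter iff the interval midpoint lies within `threshold` bp (inclusive)
#' of the nearest TSS; 1.5 kb by default, the screen's promoter definition.
#'
#' @param x A `GRanges` of fragments or sites.
#' @param tss A non-empty width-1 `GRanges` of transcription start sites.
#' @param threshold Distance cutoff in bp (inclusive).
#' @return Character vector, `"promoter"` or `"distal"`, one per interval.
#' @export
classify_promoter_distal <- function(x, tss, threshold = 1500L) {
  if (length(tss) == 0L) stop("TSS set must be non-empty")
  d <- .nearest_tss_distance(x, tss)$distance
  ifelse(!is.na(d) & d <= threshold, "promoter", "distal")
}

#' Call enhancer-positive sites from positive fragments (one replicate)
#'
#' A site is positive iff at least one distinct positive fragment (YFP bin
#' low/medium/high) overlaps it; `n_positive_fragments` counts those
#' fragments. Negative-bin fragments never score.
#'
#' @param sites A `GRanges` of open-chromatin sites (named by site id).
#' @param fragments A filtered `GRanges` with a `yfp_bin` metadata column.
#' @return A `site_call` data frame: `site_id`, `chrom`, `start`, `end`,
#'   `call` (`"positive"` or `"negative"`), `n_positive_fragments`.
#' @export
call_sites <- function(sites, fragments) {
  bins <- GenomicRanges::mcols(fragments)$yfp_bin
  if (is.null(bins)) stop("fragments need a yfp_bin metadata column")
  stopifnot(all(bins %in% .YFP_BINS))
  pos <- dedupe(fragments[bins %in% .POSITIVE_BINS])
  n <- GenomicRanges::countOverlaps(sites, pos)
  data.frame(
    site_id = if (!is.null(names(sites))) names(sites)
      else sprintf("site%05d", seq_along(sites)),
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites),
    end = GenomicRanges::end(sites),
    call = ifelse(n >= 1L, "positive", "negative"),
    n_positive_fragments = n,
    stringsAsFactors = FALSE
  )
}

#' Replicate-consensus site calls
#'
#' Consensus positive iff positive in both replicates (strict site-level
#' intersection). The two tables must cover the same site universe.
#'
#' @param call_rep1,call_rep2 `site_call` tables from [call_sites()].
#' @return A consensus table with per-replicate support columns `rep1`,
#'   `rep2` and `n_positive_fragments` summed over replicates.
#' @export
replicate_consensus <- function(call_rep1, call_rep2) {
  if (!identical(call_rep1$site_id, call_rep2$site_id) ||
      !identical(call_rep1$start, call_rep2$start)) {
    stop("replicate call tables cover different site universes")
  }
  both <- call_rep1$call == "positive" & call_rep2$call == "positive"
  data.frame(
    site_id = call_rep1$site_id,
    chrom = call_rep1$chrom, start = call_rep1$start, end = call_rep1$end,
    call = ifelse(both, "positive", "negative"),
    rep1 = call_rep1$call == "positive",
    rep2 = call_rep2$call == "positive",
    n_positive_fragments = call_rep1$n_positive_fragments +
      call_rep2$n_positive_fragments,
    stringsAsFactors = FALSE
  )
}

#' Binarize per-stage consensus calls into an activity matrix
#'
#' Builds the cross-stage site union by single-linkage merging of overlapping
#' per-stage sites (the merged element inherits the union span), marks each
#' union element 1 at a stage iff it overlaps a consensus-positive site of
#' that stage, and derives the activity pattern code (e.g. `"00111"` over
#' ES, HB, HE1, HE2, HP). Rows are sorted by pattern code, then coordinates.
#'
#' @param consensus_tables Named list (one per stage, in stage order) of
#'   consensus tables from [replicate_consensus()].
#' @return A list with `sites` (union `GRanges`) and `matrix` (data frame:
#'   `site_id`, coordinates, one 0/1 column per stage, `pattern`).
#' @export
binarize_activity <- function(consensus_tables) {
  stages <- names(consensus_tables)
  stopifnot(length(stages) >= 1L)
  as_gr <- function(tab, positive_only = FALSE) {
    if (positive_only) tab <- tab[tab$call == "positive", ]
    GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
  }
  all_sites <- do.call(c, unname(lapply(consensus_tables, as_gr)))
  union <- GenomicRanges::reduce(sort_intervals(all_sites))
  mat <- matrix(0L, length(union), length(stages),
                dimnames = list(NULL, stages))
  for (st in stages) {
    posr <- as_gr(consensus_tables[[st]], positive_only = TRUE)
    mat[, st] <- as.integer(
      GenomicRanges::countOverlaps(union, posr) > 0L)
  }
  pattern <- apply(mat, 1L, paste, collapse = "")
  df <- data.frame(
    site_id = sprintf("union%05d", seq_along(union)),
    chrom = as.character(GenomicRanges::seqnames(union)),
    start = GenomicRanges::start(union),
    end = GenomicRanges::end(union),
    mat, pattern, stringsAsFactors = FALSE, check.names = FALSE
  )
  ord <- order(df$pattern, df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, ]
  rownames(df) <- NULL
  names(union) <- sprintf("union%05d", seq_along(union))
  list(sites = union[df$site_id], matrix = df)
}

#' Stage-exclusive site sets from an activity matrix
#'
#' A site is stage-specific iff it is active in exactly one stage.
#'
#' @param activity Output of [binarize_activity()].
#' @return Named list of `GRanges`, one per stage, of stage-exclusive active
#'   sites.
#' @export
stage_specific_sets <- function(activity) {
  df <- activity$matrix
  stages <- setdiff(colnames(df),
                    c("site_id", "chrom", "start", "end", "pattern"))
  n_active <- rowSums(df[, stages, drop = FALSE])
  out <- lapply(stages, function(st) {
    ids <- df$site_id[n_active == 1L & df[[st]] == 1L]
    activity$sites[names(activity$sites) %in% ids]
  })
  stats::setNames(out, stages)
}

#' Median positive-fragment support over distal positive sites
#'
#' @param call_table A consensus or single-replicate `site_call` table.
#' @param class Character vector, `"promoter"`/`"distal"` per site (from
#'   [classify_promoter_distal()] on the site intervals).
#' @return The median `n_positive_fragments` over distal positive sites
#'   (`NA` if there are none).
#' @export
positive_fragment_median <- function(call_table, class) {
  stopifnot(length(class) == nrow(call_table))
  keep <- call_table$call == "positive" & class == "distal"
  if (!any(keep)) return(NA_real_)
  stats::median(call_table$n_positive_fragments[keep])
}

#' Run the full screen-calling pipeline
#'
#' For every stage and replicate: deduplicate, remove perfect-overlap
#' background artifacts, restrict to the stage's open chromatin (audited in a
#' filter ledger where input = retained + removed at every step), call sites
#' per replicate, intersect replicates, and binarize across stages.
#'
#' @param fragments Nested list `stage -> replicate` of `GRanges` with
#'   `yfp_bin` metadata (as produced by [gen_fragments()], or built from
#'   per-bin BED files).
#' @param background A deduplicated background-artifact `GRanges`.
#' @param sites_by_stage Named list of per-stage site `GRanges`.
#' @param tss A `GRanges` of TSS (for the promoter/distal site classes).
#' @return A list with `activity` (from [binarize_activity()]), `consensus`
#'   (per-stage tables), `calls` (per stage/replicate), `ledger` (per
#'   stage/replicate named counts) and `site_class` (per-stage
#'   promoter/distal labels).
#' @export
call_screen <- function(fragments, background, sites_by_stage, tss) {
  stages <- names(sites_by_stage)
  ledger <- list()
  calls <- list()
  consensus <- list()
  for (st in stages) {
    reps <- fragments[[st]]
    calls[[st]] <- list()
    ledger[[st]] <- list()
    for (r in seq_along(reps)) {
      fr <- reps[[r]]
      n_in <- length(fr)
      fr <- dedupe(fr)
      n_dd <- length(fr)
      bg <- remove_background(fr, background)
      oc <- restrict_to_open_chromatin(bg$fragments, sites_by_stage[[st]])
      ledger[[st]][[r]] <- c(
        input = n_in,
        duplicates = n_in - n_dd,
        background_perfect_overlap = bg$removed,
        outside_open_chromatin = oc$removed,
        retained = length(oc$fragments)
      )
      calls[[st]][[r]] <- call_sites(sites_by_stage[[st]], oc$fragments)
    }
    consensus[[st]] <- Reduce(replicate_consensus, calls[[st]])
  }
  activity <- binarize_activity(consensus)
  site_class <- lapply(sites_by_stage, classify_promoter_distal, tss = tss)
  list(activity = activity, consensus = consensus, calls = calls,
       ledger = ledger, site_class = site_class)
}

#' Check filter-ledger conservation
#'
#' Asserts `input = duplicates + background + outside_open_chromatin +
#' retained` for every stage and replicate.
#'
#' @param ledger The `ledger` element of a [call_screen()] result.
#' @return `TRUE` invisibly; errors if any entry does not reconcile.
#' @export
check_ledger <- function(ledger) {
  for (st in names(ledger)) {
    for (r in seq_along(ledger[[st]])) {
      e <- ledger[[st]][[r]]
      if (e[["input"]] != e[["duplicates"]] +
          e[["background_perfect_overlap"]] +
          e[["outside_open_chromatin"]] + e[["retained"]]) {
        stop("filter ledger does not reconcile for ", st, " replicate ", r)
      }
    }
  }
  invisible(TRUE)
}
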