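# Synthetic enhancer screen with known ground truth.
#
# The generator emulates the study conditions of a chromatin-integrated
# reporter screen over five differentiation stages (ES, HB, HE1, HE2, HP):
# stage-specific open-chromatin sites, activity-labelled 350-650 bp fragments
# sorted into four YFP bins in two replicates, PCR background artifacts,
# planted motif co-localizations, negative-binomial count tables with planted
# fold changes, and partial enhancer-gene interaction coverage. Every emitted
# record is traceable to a truth row, so downstream modules can be scored for
# exact recovery.

.default_motifs <- function() {
  data.frame(
    name  = c("AP1", "RUNX", "GATA", "PU1", "TEAD", "SOX", "OCT", "SMAD",
              "RBPJ", "CEBP", "ETS", "CTCF"),
    width = c(11L, 8L, 8L, 10L, 9L, 9L, 10L, 8L, 9L, 10L, 10L, 15L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic screen generator
#'
#' Collects every tunable of the simulation with defaults matching the screen
#' being emulated: five stages, 350-650 bp size-selected fragments, four YFP
#' sort bins, two replicates. All randomness derives from `seed`; the same
#' config yields byte-identical outputs.
#'
#' @param seed Integer master seed.
#' @param n_chroms,chrom_len Number of chromosomes and their common length
#'   (bp).
#' @param n_genes Number of genes/TSS across the genome.
#' @param n_sites_per_stage Open-chromatin sites per stage.
#' @param stages Ordered stage names.
#' @param frag_len_range Inclusive fragment length bounds in bp (size
#'   selection window of the cloned library).
#' @param frags_per_site_mean Mean positive fragments per active site per
#'   replicate (each active site emits at least one).
#' @param neg_frags_per_site_mean Mean negative-bin fragments per open site
#'   per replicate.
#' @param true_positive_fraction Probability that an open site is truly
#'   active at a stage; scalar or one value per stage.
#' @param duplicate_rate Probability that an emitted fragment gains one exact
#'   PCR duplicate in the same file.
#' @param background_artifact_rate Fraction of each sample file spiked with
#'   verbatim copies of background-library fragments.
#' @param n_background Size of the standalone background artifact library.
#' @param stage_overlap Fraction of each stage's sites shared by all stages
#'   (1 = identical site sets, 0 = fully stage-exclusive).
#' @param site_width_range Site width bounds in bp.
#' @param site_gap_min Minimum gap between adjacent sites; kept above the
#'   largest fragment half-length so a fragment can only overlap its source
#'   site.
#' @param motifs Data frame with columns `name`, `width`: the motif
#'   catalogue.
#' @param baseline_motif_rate Poisson mean of hits per motif per site.
#' @param baseline_pair_rate Poisson mean of baseline co-localized pairs per
#'   site implied by `baseline_motif_rate` (used to scale planting).
#' @param planted_pairs Data frame with columns `motif_a`, `motif_b`,
#'   `stage`, `multiplier`, `max_dist`: motif pairs planted in
#'   stage-exclusive sites at `multiplier` times the baseline pair rate,
#'   centers at most `max_dist` bp apart.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion of
#'   accessibility counts (`variance = mean + dispersion * mean^2`).
#' @param planted_fold,planted_fraction Fold change applied in condition B to
#'   a random `planted_fraction` of sites in the count tables.
#' @param interaction_coverage Fraction of true enhancer-gene links emitted
#'   as interaction anchor pairs; the rest must be recovered by nearest-TSS
#'   fallback.
#' @param nearest_gene_prob Probability that a site's true target gene is its
#'   nearest TSS (otherwise a random same-chromosome gene).
#' @param expr_high,expr_low,expr_sd Expression means for stages where a
#'   gene has >= 1 active linked enhancer vs not, and the Gaussian noise sd.
#' @param n_replicates Screen replicates per stage.
#' @param tss_spacing TSS slot spacing in bp; adjacent TSS are at least half
#'   a slot apart, so the default keeps +/- 1.5 kb promoter windows disjoint.
#' @param tss_clearance Minimum distance between any site edge and any TSS,
#'   so candidate enhancer sites are unambiguously distal.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_len = 1e7,
                       n_genes = 300L,
                       n_sites_per_stage = 500L,
                       stages = c("ES", "HB", "HE1", "HE2", "HP"),
                       frag_len_range = c(350L, 650L),
                       frags_per_site_mean = 4,
                       neg_frags_per_site_mean = 2,
                       true_positive_fraction = 0.4,
                       duplicate_rate = 0.3,
                       background_artifact_rate = 0.01,
                       n_background = 1000L,
                       stage_overlap = 0.5,
                       site_width_range = c(200L, 1000L),
                       site_gap_min = 700L,
                       motifs = .default_motifs(),
                       baseline_motif_rate = 0.5,
                       baseline_pair_rate = 0.1,
                       planted_pairs = NULL,
                       nb_mean = 100,
                       nb_dispersion = 0.05,
                       planted_fold = 4,
                       planted_fraction = 0.1,
                       interaction_coverage = 0.7,
                       nearest_gene_prob = 0.7,
                       expr_high = 8,
                       expr_low = 2,
                       expr_sd = 1,
                       n_replicates = 2L,
                       tss_spacing = 8000L,
                       tss_clearance = 2000L) {
  cfg <- as.list(environment())
  if (length(cfg$true_positive_fraction) == 1L) {
    cfg$true_positive_fraction <-
      stats::setNames(rep(cfg$true_positive_fraction, length(stages)), stages)
  } else {
    stopifnot(length(cfg$true_positive_fraction) == length(stages))
    names(cfg$true_positive_fraction) <- stages
  }
  rates <- c(cfg$true_positive_fraction, cfg$duplicate_rate,
             cfg$background_artifact_rate, cfg$stage_overlap,
             cfg$interaction_coverage, cfg$nearest_gene_prob,
             cfg$planted_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$frag_len_range[1] <= 0 || cfg$frag_len_range[2] >= cfg$chrom_len) {
    stop("frag_len_range must lie within (0, chrom_len)")
  }
  if (is.null(cfg$planted_pairs)) {
    cfg$planted_pairs <- data.frame(motif_a = character(),
                                    motif_b = character(),
                                    stage = character(),
                                    multiplier = numeric(),
                                    max_dist = integer(),
                                    stringsAsFactors = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# sub-seed discipline: each generator stage reseeds from the master seed plus
# a fixed offset, so stages are individually reproducible and the whole run
# is deterministic no matter which subset of generators is invoked.
.sim_seed <- function(config, offset) {
  set.seed((as.integer(config$seed) %% 1000000L) * 1000L + offset)
}

#' Generate gene annotation for the synthetic genome
#'
#' Places `n_genes` TSS across the chromosomes (proportional to length) with
#' minimum spacing enforced by slotting one TSS per `tss_spacing` window and
#' jittering within the first half of the slot.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (data frame `chrom`, `length`) and `tss`
#'   (width-1 `GRanges` named by gene id, with `gene_id` metadata).
#' @export
gen_annotation <- function(config) {
  .sim_seed(config, 1L)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- data.frame(chrom = chroms, length = config$chrom_len)
  n <- config$n_genes
  if (n == 0L) {
    return(list(genome = genome,
                tss = GenomicRanges::GRanges()))
  }
  margin <- 10000L
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1L)))
  pos <- character(0); chrv <- character(0)
  all_pos <- integer(0); all_chr <- character(0)
  for (i in seq_len(config$n_chroms)) {
    k <- per_chrom[i]
    if (k == 0L) next
    slots <- seq(margin, config$chrom_len - margin, by = config$tss_spacing)
    if (k > length(slots)) stop("n_genes too large for tss_spacing")
    starts <- sort(sample(slots, k))
    jitter <- sample.int(max(1L, config$tss_spacing %/% 2L), k, replace = TRUE)
    all_pos <- c(all_pos, as.integer(starts + jitter))
    all_chr <- c(all_chr, rep(chroms[i], k))
  }
  gene_id <- sprintf("gene%04d", seq_len(n))
  tss <- GenomicRanges::GRanges(all_chr, IRanges::IRanges(all_pos, all_pos),
                                strand = sample(c("+", "-"), n, TRUE))
  names(tss) <- gene_id
  GenomicRanges::mcols(tss)$gene_id <- gene_id
  list(genome = genome, tss = tss)
}

#' Generate per-stage open-chromatin sites with ground-truth activity
#'
#' Builds a pool of non-overlapping sites (width within
#' `site_width_range`, gaps >= `site_gap_min`), of which a `stage_overlap`
#' fraction is shared by all stages and the remainder is stage-exclusive, so
#' both constitutive and stage-specific sites exist. Each open (site, stage)
#' cell is truly active with probability `true_positive_fraction[stage]`.
#' Each site gets a summit (uniform within the site), a promoter/distal class
#' (1.5 kb midpoint-to-TSS rule), and a true target gene (nearest TSS with
#' probability `nearest_gene_prob`, otherwise a random same-chromosome gene).
#'
#' @param config A [sim_config()].
#' @param annotation Output of [gen_annotation()].
#' @return A list with `pool` (all sites, a `GRanges` named by site id with
#'   `summit` metadata), `sites_by_stage` (named list of per-stage
#'   `GRanges`), and `truth`: `open` and `activity` (site x stage 0/1
#'   matrices), `class` (promoter/distal), `linked_gene`.
#' @export
gen_sites <- function(config, annotation) {
  .sim_seed(config, 2L)
  stages <- config$stages
  n_shared <- round(config$stage_overlap * config$n_sites_per_stage)
  n_excl <- config$n_sites_per_stage - n_shared
  n_pool <- n_shared + n_excl * length(stages)
  widths <- sample(seq(config$site_width_range[1], config$site_width_range[2]),
                   n_pool, replace = TRUE)
  gaps <- config$site_gap_min +
    sample.int(config$site_gap_min, n_pool, replace = TRUE)
  margin <- 2000L
  chroms <- annotation$genome$chrom
  cap <- config$chrom_len - 2L * margin
  # sites are spread over the whole of each chromosome: minimum gaps keep
  # fragments from bridging neighbouring sites, the remaining slack is
  # distributed uniformly, and candidate sites keep tss_clearance bp away
  # from every TSS so promoter windows never brush a site and linking truth
  # stays unambiguous
  tss_chr <- as.character(GenomicRanges::seqnames(annotation$tss))
  tss_pos <- GenomicRanges::start(annotation$tss)
  clearance <- config$tss_clearance
  per_chrom <- diff(round(seq(0, n_pool, length.out = length(chroms) + 1L)))
  site_chr <- character(n_pool); site_start <- integer(n_pool)
  done <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    idx <- done + seq_len(k)
    # reserve room for detours around TSS exclusion zones
    tss_budget <- sum(tss_chr == chroms[ci]) *
      (2L * clearance + max(widths[idx]))
    slack <- (config$chrom_len - 2L * margin) - sum(widths[idx]) -
      sum(gaps[idx]) - tss_budget
    if (slack < 0) stop("genome too small for requested number of sites")
    extra <- diff(c(0, sort(stats::runif(k, 0, slack))))
    tp <- sort(tss_pos[tss_chr == chroms[ci]])
    cursor <- margin
    for (j in seq_len(k)) {
      i <- idx[j]
      cursor <- cursor + extra[j]
      repeat {
        conflict <- tp[tp >= cursor - clearance &
                         tp <= cursor + widths[i] + clearance]
        if (length(conflict) == 0L) break
        cursor <- max(conflict) + clearance + 1
      }
      if (cursor + widths[i] > config$chrom_len - margin) {
        stop("genome too small for requested number of sites")
      }
      site_chr[i] <- chroms[ci]
      site_start[i] <- as.integer(cursor)
      cursor <- cursor + widths[i] + gaps[i]
    }
    done <- done + k
  }
  pool <- GenomicRanges::GRanges(site_chr,
                                 IRanges::IRanges(site_start,
                                                  width = widths))
  site_id <- sprintf("site%05d", seq_len(n_pool))
  names(pool) <- site_id
  GenomicRanges::mcols(pool)$summit <- GenomicRanges::start(pool) +
    vapply(widths, function(w) sample.int(w, 1L) - 1L, integer(1))

  # stage membership: shuffle, first block shared by all stages, then one
  # exclusive block per stage
  perm <- sample.int(n_pool)
  open <- matrix(0L, n_pool, length(stages),
                 dimnames = list(site_id, stages))
  shared_idx <- perm[seq_len(n_shared)]
  open[shared_idx, ] <- 1L
  off <- n_shared
  for (s in seq_along(stages)) {
    if (n_excl > 0L) {
      open[perm[(off + 1L):(off + n_excl)], s] <- 1L
      off <- off + n_excl
    }
  }
  activity <- open
  for (s in seq_along(stages)) {
    is_open <- open[, s] == 1L
    activity[is_open, s] <-
      stats::rbinom(sum(is_open), 1L,
                    config$true_positive_fraction[[stages[s]]])
  }
  cls <- if (length(annotation$tss) > 0L) {
    classify_promoter_distal(pool, annotation$tss)
  } else rep("distal", n_pool)
  linked_gene <- rep(NA_character_, n_pool)
  if (length(annotation$tss) > 0L) {
    nearest <- nearest_gene(pool, annotation$tss)$gene_id
    use_near <- stats::rbinom(n_pool, 1L, config$nearest_gene_prob) == 1L
    linked_gene[use_near] <- nearest[use_near]
    tss_chr <- as.character(GenomicRanges::seqnames(annotation$tss))
    for (i in which(!use_near)) {
      cand <- GenomicRanges::mcols(annotation$tss)$gene_id[
        tss_chr == site_chr[i]]
      linked_gene[i] <- if (length(cand)) sample(cand, 1L) else nearest[i]
    }
  }
  sites_by_stage <- lapply(seq_along(stages), function(s) {
    sort_intervals(pool[open[, s] == 1L])
  })
  names(sites_by_stage) <- stages
  list(pool = sort_intervals(pool), sites_by_stage = sites_by_stage,
       truth = list(open = open, activity = activity, class = cls,
                    linked_gene = stats::setNames(linked_gene, site_id)))
}

.emit_site_fragments <- function(pool, idx, bins, config) {
  # one fragment per row of (idx, bins): length uniform in frag_len_range,
  # midpoint uniform within the source site so the fragment always overlaps it
  n <- length(idx)
  L <- sample(seq(config$frag_len_range[1], config$frag_len_range[2]),
              n, replace = TRUE)
  w <- GenomicRanges::width(pool)[idx]
  centers <- GenomicRanges::start(pool)[idx] +
    floor(stats::runif(n) * w)
  s <- pmax(1L, as.integer(centers - L %/% 2L))
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(pool))[idx],
    IRanges::IRanges(s, width = L))
  GenomicRanges::mcols(gr)$yfp_bin <- bins
  GenomicRanges::mcols(gr)$site_id <- names(pool)[idx]
  gr
}

#' Generate activity-labelled screen fragments plus background artifacts
#'
#' Truly active sites emit positive fragments (low/medium/high YFP bins) in
#' every replicate; all open sites additionally emit negative-bin fragments.
#' Exact PCR duplicates are injected at `duplicate_rate`. A standalone
#' background library of site-independent fragments is generated and a
#' `background_artifact_rate` fraction of each sample file is spiked with
#' verbatim copies of it, so perfect-overlap background removal is exercised.
#'
#' @param config A [sim_config()].
#' @param sites Output of [gen_sites()].
#' @return A list with `fragments` (nested list `stage -> replicate` of
#'   `GRanges` with `yfp_bin`, `site_id`, `is_duplicate`, `is_background`
#'   metadata), `background` (a `GRanges`), and `truth` (per stage/replicate
#'   counts of site-derived, duplicate and background-injected fragments).
#' @export
gen_fragments <- function(config, sites) {
  .sim_seed(config, 3L)
  stages <- config$stages
  pool <- sites$pool
  act <- sites$truth$activity[names(pool), , drop = FALSE]
  open <- sites$truth$open[names(pool), , drop = FALSE]

  # background library: uniform over the genome, independent of sites
  nb <- config$n_background
  bl <- sample(seq(config$frag_len_range[1], config$frag_len_range[2]),
               nb, replace = TRUE)
  bchr <- paste0("chr", sample.int(config$n_chroms, nb, replace = TRUE))
  bstart <- as.integer(floor(stats::runif(nb, 1, config$chrom_len - bl)))
  background <- dedupe(GenomicRanges::GRanges(bchr,
                                              IRanges::IRanges(bstart,
                                                               width = bl)))

  fragments <- list()
  truth <- list()
  for (st in stages) {
    fragments[[st]] <- list()
    for (rep_i in seq_len(config$n_replicates)) {
      active_idx <- which(act[, st] == 1L)
      open_idx <- which(open[, st] == 1L)
      # positive fragments: >= 1 per active site
      n_pos <- 1L + stats::rpois(length(active_idx),
                                 max(0, config$frags_per_site_mean - 1))
      pos_idx <- rep(active_idx, n_pos)
      pos_bins <- sample(c("low", "medium", "high"), length(pos_idx),
                         replace = TRUE)
      # negative fragments from every open site (non-scoring evidence)
      n_neg <- stats::rpois(length(open_idx), config$neg_frags_per_site_mean)
      neg_idx <- rep(open_idx, n_neg)
      gr <- .emit_site_fragments(pool, c(pos_idx, neg_idx),
                                 c(pos_bins, rep("negative", length(neg_idx))),
                                 config)
      GenomicRanges::mcols(gr)$is_duplicate <- FALSE
      GenomicRanges::mcols(gr)$is_background <- FALSE
      # PCR duplicates: exact copies
      dup <- stats::rbinom(length(gr), 1L, config$duplicate_rate) == 1L
      dups <- gr[dup]
      if (length(dups)) GenomicRanges::mcols(dups)$is_duplicate <- TRUE
      # background spike-ins: verbatim coordinates from the background library
      n_spike <- round(config$background_artifact_rate *
                         (length(gr) + length(dups)))
      spikes <- GenomicRanges::GRanges()
      if (n_spike > 0L && length(background) > 0L) {
        spikes <- background[sample.int(length(background), n_spike,
                                        replace = TRUE)]
        GenomicRanges::mcols(spikes) <- S4Vectors::DataFrame(
          yfp_bin = sample(c("negative", "low", "medium", "high"),
                           n_spike, replace = TRUE),
          site_id = NA_character_,
          is_duplicate = FALSE,
          is_background = TRUE)
        names(spikes) <- NULL
      }
      out <- c(gr, dups, spikes)
      fragments[[st]][[rep_i]] <- sort_intervals(out)
      truth[[st]][[rep_i]] <- c(site_derived = length(gr),
                                duplicates = length(dups),
                                background_injected = length(spikes),
                                total = length(out))
    }
  }
  list(fragments = fragments, background = background, truth = truth)
}

#' Generate motif hit coordinates with planted co-localizations
#'
#' Baseline hits per (motif, site) are Poisson(`baseline_motif_rate`), placed
#' uniformly within the site. For each row of `planted_pairs`, extra
#' explicitly co-located hit pairs (centers at most `max_dist` bp apart) are
#' inserted into the target stage's exclusive sites at rate
#' `(multiplier - 1) * baseline_pair_rate` per site, so the total pair
#' frequency sits at `multiplier` times baseline and a multiplier of 1 plants
#' nothing.
#'
#' @param config A [sim_config()].
#' @param sites Output of [gen_sites()].
#' @return A list with `hits` (named list of `GRanges`, one per motif) and
#'   `planted` (the planted-pair truth table with per-pair inserted counts).
#' @export
gen_motif_hits <- function(config, sites) {
  .sim_seed(config, 4L)
  pool <- sites$pool
  motifs <- config$motifs
  if (any(motifs$width > min(GenomicRanges::width(pool)))) {
    stop("motif width exceeds the narrowest site width")
  }
  n_pool <- length(pool)
  chr <- as.character(GenomicRanges::seqnames(pool))
  s0 <- GenomicRanges::start(pool)
  w <- GenomicRanges::width(pool)
  hits <- list()
  for (m in seq_len(nrow(motifs))) {
    mw <- motifs$width[m]
    k <- stats::rpois(n_pool, config$baseline_motif_rate)
    idx <- rep(seq_len(n_pool), k)
    if (length(idx) == 0L) {
      hits[[motifs$name[m]]] <- GenomicRanges::GRanges()
      next
    }
    start <- s0[idx] + floor(stats::runif(length(idx)) * (w[idx] - mw + 1L))
    hits[[motifs$name[m]]] <-
      sort_intervals(GenomicRanges::GRanges(chr[idx],
                                            IRanges::IRanges(as.integer(start),
                                                             width = mw)))
  }
  planted <- config$planted_pairs
  planted$n_inserted <- integer(nrow(planted)) + 0L
  planted$n_deleted_a <- integer(nrow(planted)) + 0L
  planted$n_deleted_b <- integer(nrow(planted)) + 0L
  if (nrow(planted) > 0L) {
    open <- sites$truth$open
    for (p in seq_len(nrow(planted))) {
      st <- planted$stage[p]
      stopifnot(st %in% config$stages)
      excl <- open[, st] == 1L & rowSums(open) == 1L
      target <- which(names(pool) %in% rownames(open)[excl])
      rate <- max(0, (planted$multiplier[p] - 1) * config$baseline_pair_rate)
      if (rate == 0 || length(target) == 0L) next
      k <- stats::rpois(length(target), rate)
      idx <- rep(target[k > 0L], k[k > 0L])
      if (length(idx) == 0L) next
      ma <- planted$motif_a[p]; mb <- planted$motif_b[p]
      wa <- motifs$width[match(ma, motifs$name)]
      wb <- motifs$width[match(mb, motifs$name)]
      if (is.na(wa) || is.na(wb)) stop("planted pair names unknown motif")
      # anchor center uniform within the site, partner offset <= max_dist
      ca <- s0[idx] + floor(stats::runif(length(idx)) * w[idx])
      off <- sample.int(planted$max_dist[p], length(idx), replace = TRUE)
      mk <- function(centers, mw) {
        st_ <- pmax(s0[idx], pmin(as.integer(centers - mw %/% 2L),
                                  s0[idx] + w[idx] - mw))
        GenomicRanges::GRanges(chr[idx], IRanges::IRanges(st_, width = mw))
      }
      # marginal-preserving planting: each inserted pair event removes one
      # baseline hit of each motif from the target sites (when available),
      # so per-motif hit rates stay at baseline and only the pair
      # co-localization is boosted
      drop_baseline <- function(motif, n_events) {
        h <- hits[[motif]]
        in_target <- GenomicRanges::countOverlaps(h, pool[target]) > 0L
        avail <- which(in_target)
        n_del <- min(length(avail), n_events)
        if (n_del > 0L) {
          hits[[motif]] <<- h[-sample(avail, n_del)]
        }
        n_del
      }
      planted$n_deleted_a[p] <- drop_baseline(ma, length(idx))
      planted$n_deleted_b[p] <- drop_baseline(mb, length(idx))
      hits[[ma]] <- sort_intervals(c(hits[[ma]], mk(ca, wa)))
      hits[[mb]] <- sort_intervals(c(hits[[mb]], mk(ca + off, wb)))
      planted$n_inserted[p] <- length(idx)
    }
  }
  list(hits = hits, planted = planted)
}

#' Generate replicate accessibility count tables with planted fold changes
#'
#' Counts are negative-binomial with mean `nb_mean` and dispersion
#' `nb_dispersion` per site per replicate in two conditions (A, B); a random
#' `planted_fraction` of sites has its condition-B mean multiplied by
#' `planted_fold`.
#'
#' @param config A [sim_config()].
#' @param site_union A `GRanges` of union sites (row universe).
#' @return A list with `counts` (matrix sites x samples, columns `A_1, A_2,
#'   B_1, B_2`), `condition`, `replicate` (per-column labels) and `truth`
#'   (`planted` logical, `fold` per site).
#' @export
gen_counts <- function(config, site_union) {
  .sim_seed(config, 5L)
  n <- length(site_union)
  n_planted <- round(config$planted_fraction * n)
  planted <- rep(FALSE, n)
  planted[sample.int(n, n_planted)] <- TRUE
  fold <- ifelse(planted, config$planted_fold, 1)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  draw <- function(mu) {
    if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
    else stats::rpois(n, mu)
  }
  counts <- cbind(A_1 = draw(rep(config$nb_mean, n)),
                  A_2 = draw(rep(config$nb_mean, n)),
                  B_1 = draw(config$nb_mean * fold),
                  B_2 = draw(config$nb_mean * fold))
  rownames(counts) <- if (!is.null(names(site_union))) names(site_union)
    else sprintf("site%05d", seq_len(n))
  list(counts = counts,
       condition = c("A", "A", "B", "B"),
       replicate = c(1L, 2L, 1L, 2L),
       truth = data.frame(site_id = rownames(counts), planted = planted,
                          fold = fold, stringsAsFactors = FALSE))
}

#' Generate interaction anchor pairs and a stage expression table
#'
#' Emits a `interaction_coverage` fraction of the true enhancer-to-gene links
#' as anchor pairs (enhancer interval vs TSS +/- 1500 bp promoter window);
#' the remainder is left for nearest-TSS fallback. Gene expression per stage
#' is `expr_high` when the gene has at least one truly active linked
#' enhancer at that stage and `expr_low` otherwise, plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param sites Output of [gen_sites()].
#' @param annotation Output of [gen_annotation()].
#' @return A list with `interactions` (list: `anchor1`, `anchor2` parallel
#'   `GRanges`, `source` tag), `expression` (gene x stage matrix), and
#'   `truth` (data frame of all true links with `covered` flag).
#' @export
gen_interactions <- function(config, sites, annotation) {
  .sim_seed(config, 6L)
  pool <- sites$pool
  lg <- sites$truth$linked_gene[names(pool)]
  links <- data.frame(site_id = names(pool), gene_id = unname(lg),
                      stringsAsFactors = FALSE)
  links <- links[!is.na(links$gene_id), ]
  n_cov <- round(config$interaction_coverage * nrow(links))
  covered <- rep(FALSE, nrow(links))
  if (n_cov > 0L) covered[sample.int(nrow(links), n_cov)] <- TRUE
  links$covered <- covered
  tss <- annotation$tss
  prom <- promoter_windows(tss)
  ix1 <- pool[links$site_id[covered]]
  ix2 <- prom[match(links$gene_id[covered],
                    GenomicRanges::mcols(prom)$gene_id)]
  src <- sample(c("ES", "HP"), sum(covered), replace = TRUE)
  act <- sites$truth$activity
  genes <- GenomicRanges::mcols(tss)$gene_id
  expr <- matrix(config$expr_low, length(genes), length(config$stages),
                 dimnames = list(genes, config$stages))
  for (st in config$stages) {
    active_sites <- rownames(act)[act[, st] == 1L]
    hi <- unique(links$gene_id[links$site_id %in% active_sites])
    expr[rownames(expr) %in% hi, st] <- config$expr_high
  }
  expr <- expr + matrix(stats::rnorm(length(expr), 0, config$expr_sd),
                        nrow(expr))
  list(interactions = list(anchor1 = ix1, anchor2 = ix2, source = src),
       expression = expr,
       truth = links)
}

#' Run the whole synthetic screen generator
#'
#' Convenience wrapper calling [gen_annotation()], [gen_sites()],
#' [gen_fragments()], [gen_motif_hits()], [gen_counts()] and
#' [gen_interactions()] under one config. Deterministic: the same config
#' yields identical output.
#'
#' @param config A [sim_config()].
#' @return A named list with all generator outputs plus the config.
#' @export
simulate_screen <- function(config = sim_config()) {
  annotation <- gen_annotation(config)
  sites <- gen_sites(config, annotation)
  frags <- gen_fragments(config, sites)
  motifs <- gen_motif_hits(config, sites)
  counts <- gen_counts(config, sites$pool)
  inter <- gen_interactions(config, sites, annotation)
  list(config = config, annotation = annotation, sites = sites,
       fragments = frags$fragments, background = frags$background,
       fragment_truth = frags$truth,
       motif_hits = motifs$hits, planted_pairs = motifs$planted,
       counts = counts, interactions = inter)
}
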