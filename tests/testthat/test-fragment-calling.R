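test_that("background removal requires a perfect coordinate match", {
  bg <- bed_gr("chr1", 100, 500)
  expect_identical(remove_background(bed_gr("chr1", 100, 500), bg)$removed, 1L)
  res <- remove_background(bed_gr("chr1", 100, 501), bg)
  expect_identical(res$removed, 0L)
  expect_length(res$fragments, 1L)
  # empty background is the identity
  fr <- bed_gr(c("chr1", "chr2"), c(1, 10), c(400, 600))
  expect_length(remove_background(fr, GRanges())$fragments, 2L)
})

test_that("open-chromatin restriction keeps >=1 bp overlappers only", {
  sites <- bed_gr("chr1", c(1000, 5000), c(1600, 5800))
  fr <- bed_gr("chr1", c(1100, 3000, 5799), c(1500, 3400, 6200))
  res <- restrict_to_open_chromatin(fr, sites)
  expect_identical(res$removed, 1L)
  expect_identical(start(res$fragments), c(1101L, 5800L))
})

test_that("restriction recovers exactly the site-derived fragments", {
  sim <- small_sim(seed = 21, duplicate_rate = 0,
                   background_artifact_rate = 0)
  for (st in names(sim$fragments)) {
    fr <- sim$fragments[[st]][[1]]
    res <- restrict_to_open_chromatin(fr, sim$sites$sites_by_stage[[st]])
    expect_identical(res$removed, 0L)
    expect_identical(length(res$fragments), length(fr))
  }
})

test_that("promoter classification is inclusive at the 1.5 kb boundary", {
  tss <- bed_gr("chr1", 9999, 10000, gene_id = "g1") # TSS at base 10000
  at <- function(center) bed_gr("chr1", center - 1, center)
  expect_identical(classify_promoter_distal(at(10000), tss), "promoter")
  expect_identical(classify_promoter_distal(at(11500), tss), "promoter")
  expect_identical(classify_promoter_distal(at(11501), tss), "distal")
  expect_identical(classify_promoter_distal(at(8500), tss), "promoter")
  expect_error(classify_promoter_distal(at(1), GRanges()), "non-empty")
})

test_that("site calls require a positive-bin overlapping fragment", {
  sites <- bed_gr("chr1", c(1000, 5000), c(1600, 5800))
  names(sites) <- c("s1", "s2")
  fr <- bed_gr("chr1", c(1100, 5100, 5200), c(1500, 5500, 5600),
               yfp_bin = c("low", "negative", "negative"))
  tab <- call_sites(sites, fr)
  expect_identical(tab$call, c("positive", "negative"))
  expect_identical(tab$n_positive_fragments, c(1L, 0L))
})

test_that("replicate consensus is a strict intersection", {
  sites <- bed_gr("chr1", c(1000, 5000, 9000), c(1600, 5800, 9900))
  names(sites) <- c("s1", "s2", "s3")
  mk <- function(pos) {
    call_sites(sites, bed_gr("chr1", pos, pos + 400,
                             yfp_bin = rep("high", length(pos))))
  }
  r1 <- mk(c(1100, 5100))         # s1, s2 positive
  r2 <- mk(c(1100, 9100))         # s1, s3 positive
  cons <- replicate_consensus(r1, r2)
  expect_identical(cons$call, c("positive", "negative", "negative"))
  expect_identical(cons$rep1, c(TRUE, TRUE, FALSE))
  expect_identical(cons$rep2, c(TRUE, FALSE, TRUE))
  r3 <- mk(1100)[1, ]
  expect_error(replicate_consensus(r1, r3), "universe")
})

test_that("binarized patterns encode stage activity and sort by pattern", {
  sites <- bed_gr("chr1", c(1000, 5000), c(1600, 5800))
  names(sites) <- c("s1", "s2")
  mk <- function(pos) {
    t1 <- call_sites(sites, bed_gr("chr1", pos, pos + 400,
                                   yfp_bin = rep("low", length(pos))))
    replicate_consensus(t1, t1)
  }
  tabs <- list(ES = mk(numeric(0)), HB = mk(numeric(0)), HE1 = mk(1100),
               HE2 = mk(1100), HP = mk(c(1100, 5100)))
  act <- binarize_activity(tabs)
  expect_identical(act$matrix$pattern, c("00001", "00111"))
  expect_identical(act$matrix$start, c(5001L, 1001L)) # pattern-sorted rows
})

test_that("stage-specific sets pick single-stage patterns only", {
  sites <- bed_gr("chr1", c(1000, 5000, 9000), c(1600, 5800, 9900))
  names(sites) <- c("s1", "s2", "s3")
  mk <- function(pos) {
    t1 <- call_sites(sites, bed_gr("chr1", pos, pos + 300,
                                   yfp_bin = rep("low", length(pos))))
    replicate_consensus(t1, t1)
  }
  tabs <- list(ES = mk(numeric(0)), HB = mk(1100), HE1 = mk(c(5100, 9100)),
               HE2 = mk(5100), HP = mk(numeric(0)))
  act <- binarize_activity(tabs)
  sp <- stage_specific_sets(act)
  expect_identical(start(sp$HB), 1001L)     # pattern 01000
  expect_identical(start(sp$HE1), 9001L)    # pattern 00100
  expect_length(sp$HE2, 0L)                 # s2 has pattern 00110
})

test_that("the distal positive-fragment median matches a sorted-middle oracle", {
  set.seed(31)
  n <- 101
  tab <- data.frame(site_id = sprintf("s%03d", 1:n), chrom = "chr1",
                    start = 1:n, end = 2:(n + 1),
                    call = sample(c("positive", "negative"), n, TRUE),
                    n_positive_fragments = rpois(n, 4))
  cls <- sample(c("promoter", "distal"), n, TRUE)
  v <- sort(tab$n_positive_fragments[tab$call == "positive" &
                                       cls == "distal"])
  oracle <- if (length(v) %% 2 == 1) v[(length(v) + 1) / 2]
    else mean(v[length(v) / 2 + 0:1])
  expect_identical(positive_fragment_median(tab, cls), as.numeric(oracle))
})

test_that("adding positive fragments never turns a positive site negative", {
  sim <- small_sim(seed = 32)
  st <- "HP"
  sites <- sim$sites$sites_by_stage[[st]]
  fr <- sim$fragments[[st]][[1]]
  base <- call_sites(sites, fr)
  extra <- bed_gr(as.character(seqnames(sites))[1],
                  start(sites)[1], start(sites)[1] + 400, yfp_bin = "high")
  mcols(extra)$site_id <- NA; mcols(extra)$is_duplicate <- FALSE
  mcols(extra)$is_background <- FALSE
  more <- call_sites(sites, c(fr, extra))
  expect_true(all(!(base$call == "positive" & more$call == "negative")))
  expect_true(all(more$n_positive_fragments >= base$n_positive_fragments))
})

test_that("the pipeline is stable under input fragment permutation", {
  sim <- small_sim(seed = 33)
  shuffled <- sim$fragments
  set.seed(1)
  for (st in names(shuffled)) {
    for (r in seq_along(shuffled[[st]])) {
      fr <- shuffled[[st]][[r]]
      shuffled[[st]][[r]] <- fr[sample(length(fr))]
    }
  }
  a <- call_screen(sim$fragments, sim$background,
                   sim$sites$sites_by_stage, sim$annotation$tss)
  b <- call_screen(shuffled, sim$background,
                   sim$sites$sites_by_stage, sim$annotation$tss)
  expect_identical(a$activity$matrix, b$activity$matrix)
  expect_identical(a$ledger, b$ledger)
})

test_that("a small noiseless screen reproduces the truth matrix", {
  sim <- small_sim(seed = 34)
  res <- call_screen(sim$fragments, sim$background,
                     sim$sites$sites_by_stage, sim$annotation$tss)
  expect_true(check_ledger(res$ledger))
  df <- res$activity$matrix
  pool <- sim$sites$pool
  m <- match(paste(df$chrom, df$start, df$end),
             paste(as.character(seqnames(pool)), start(pool), end(pool)))
  expect_false(anyNA(m))
  truth <- sim$sites$truth$activity[names(pool)[m], , drop = FALSE]
  called <- as.matrix(df[, sim$config$stages])
  expect_identical(unname(called), unname(truth))
})
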