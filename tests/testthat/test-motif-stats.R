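test_that("pair counting handles the boundary and degenerate cases", {
  regions <- bed_gr("chr1", 0, 10000)
  hits <- list(A = bed_gr("chr1", 100, 110),       # midpoint 105
               B = bed_gr("chr1", 130, 140))       # midpoint 135: 30 bp away
  x <- count_motif_pairs(hits, regions, window = 50)
  expect_identical(x["A", "B"], 1L)
  expect_identical(x["A", "A"], 0L)
  # coordinate-identical hits (100% overlap) are excluded
  same <- list(A = bed_gr("chr1", 100, 110), B = bed_gr("chr1", 100, 110))
  expect_true(all(count_motif_pairs(same, regions, 50) == 0L))
  # three same-motif hits mutually within 50 bp -> C(3,2) on the diagonal
  tri <- list(A = bed_gr("chr1", c(100, 120, 140), c(110, 130, 150)))
  expect_identical(count_motif_pairs(tri, regions, 50)["A", "A"], 3L)
  # hits outside the region set are ignored
  far <- list(A = bed_gr("chr1", c(100, 20000), c(110, 20010)),
              B = bed_gr("chr1", c(130, 20030), c(140, 20040)))
  expect_identical(count_motif_pairs(far, bed_gr("chr1", 0, 1000), 50)["A", "B"],
                   1L)
  expect_error(count_motif_pairs(hits, regions, window = 0), "window")
})

test_that("pair counting equals exhaustive enumeration for several windows", {
  set.seed(51)
  regions <- bed_gr("chr1", seq(0, 99000, by = 1000),
                    seq(0, 99000, by = 1000) + 500)
  hits <- lapply(1:5, function(i) {
    s <- sample.int(1e5, 60)
    bed_gr("chr1", s, s + 10)
  })
  names(hits) <- LETTERS[1:5]
  for (w in c(10L, 50L, 200L)) {
    expect_identical(unname(count_motif_pairs(hits, regions, w))[,],
                     unname(brute_pair_count(hits, regions, w))[,])
  }
  x <- count_motif_pairs(hits, regions, 50)
  expect_identical(x, t(x))
})

test_that("the resampled null is deterministic and degenerate-safe", {
  # identical motif content in every site -> zero variance
  starts <- seq(0, 9 * 5000, by = 5000)
  hits <- list(A = bed_gr("chr1", starts + 100, starts + 110),
               B = bed_gr("chr1", starts + 120, starts + 130))
  sites <- bed_gr("chr1", starts, starts + 500)
  null <- resample_null(hits, sites, n_draw = 4, reps = 50, seed = 1)
  expect_identical(null$mu["A", "B"], 4)
  expect_identical(null$sigma["A", "B"], 0)
  null2 <- resample_null(hits, sites, n_draw = 4, reps = 50, seed = 1)
  expect_identical(null, null2)
  expect_error(resample_null(hits, sites, n_draw = 11, reps = 10), "n_draw")
  expect_error(resample_null(hits, sites, n_draw = 2, reps = 1), "reps")
})

test_that("the fast resampling index agrees with direct recounting", {
  sim <- small_sim(seed = 52)
  pool <- sim$sites$pool
  idx <- relayscreen:::.pair_index(sim$motif_hits, pool, 50)
  set.seed(9)
  for (k in 1:5) {
    draw <- sample(length(pool), 40)
    member <- rep(FALSE, length(pool)); member[draw] <- TRUE
    fast <- relayscreen:::.count_from_index(idx, member)
    direct <- count_motif_pairs(sim$motif_hits, pool[draw], 50)
    expect_identical(unname(fast)[,], unname(direct)[,])
  }
})

test_that("null moments converge as repetitions grow", {
  sim <- small_sim(seed = 53)
  pool <- sim$sites$pool
  n1 <- resample_null(sim$motif_hits, pool, n_draw = 100, reps = 500,
                      seed = 1)
  n2 <- resample_null(sim$motif_hits, pool, n_draw = 100, reps = 1000,
                      seed = 2)
  se <- n1$sigma / sqrt(n1$reps) + n2$sigma / sqrt(n2$reps)
  ok <- se > 0
  expect_true(all(abs(n1$mu[ok] - n2$mu[ok]) <= 3 * se[ok]))
})

test_that("z-scores follow the definition and cap zero-variance conflicts", {
  nm <- c("A", "B")
  mk <- function(v) matrix(v, 2, 2, dimnames = list(nm, nm))
  null <- structure(list(mu = mk(4), sigma = mk(2), reps = 100),
                    class = "pair_null")
  z <- pair_zscore(mk(c(4, 10, 10, 4)), null)
  expect_identical(z$z["A", "A"], 0)
  expect_identical(z$z["A", "B"], 3)
  null0 <- structure(list(mu = mk(4), sigma = mk(0), reps = 100),
                     class = "pair_null")
  z0 <- pair_zscore(mk(c(4, 2, 7, 4)), null0, cap = 10)
  expect_identical(z0$z["A", "A"], 0)
  expect_identical(z0$z["A", "B"], 10)
  expect_identical(z0$z["B", "A"], -10)
  expect_true(z0$capped["A", "B"])
})

test_that("adding a co-localized pair never decreases its z-score", {
  sim <- small_sim(seed = 54)
  pool <- sim$sites$pool
  draw <- pool[1:40]
  null <- resample_null(sim$motif_hits, pool, n_draw = 40, reps = 100,
                        seed = 3)
  x1 <- count_motif_pairs(sim$motif_hits, draw, 50)
  hits2 <- sim$motif_hits
  anchor <- start(draw)[1] + 50L
  hits2$AP1 <- c(hits2$AP1, GRanges("chr1", IRanges::IRanges(anchor,
                                                             anchor + 10L)))
  hits2$RUNX <- c(hits2$RUNX, GRanges("chr1", IRanges::IRanges(anchor + 20L,
                                                               anchor + 27L)))
  x2 <- count_motif_pairs(hits2, draw, 50)
  expect_gte(x2["AP1", "RUNX"], x1["AP1", "RUNX"] + 1L)
  z1 <- pair_zscore(x1, null)$z["AP1", "RUNX"]
  z2 <- pair_zscore(x2, null)$z["AP1", "RUNX"]
  expect_gte(z2, z1)
})

test_that("relative enrichment follows the score definition", {
  # printed micro-example: n = [4, 1], m = [2, 2] -> S = [1.6, 0.4]
  re <- relative_enrichment(matrix(c(4, 1), 1), c(2, 2))
  expect_equal(as.numeric(re$S), c(1.6, 0.4), tolerance = 1e-12)
  # a single peak set scores 1 for every represented motif
  one <- relative_enrichment(matrix(c(3, 0, 7), 3), 5)
  expect_equal(as.numeric(one$S[!one$undefined, ]), c(1, 1))
  expect_true(one$undefined[2])
  expect_true(all(is.na(one$S[2, ])))
  # equal per-site rates across sets -> S = 1 everywhere
  eq <- relative_enrichment(matrix(c(10, 20), 1), c(100, 200))
  expect_equal(as.numeric(eq$S), c(1, 1))
  expect_error(relative_enrichment(matrix(1:2, 1), c(2, 0)), "m_j")
})

test_that("enrichment rows conserve the set-size weighted mean", {
  set.seed(55)
  for (trial in 1:25) {
    n <- matrix(rpois(40, 5), 10, 4)
    m <- sample(50:500, 4)
    re <- relative_enrichment(n, m)
    ok <- !re$undefined
    wm <- as.numeric(re$S[ok, , drop = FALSE] %*% (m / sum(m)))
    expect_true(all(abs(wm - 1) < 1e-9))
  }
})

test_that("z-scaling standardizes the chosen axis and flags constants", {
  set.seed(56)
  m <- matrix(rnorm(50), 10, 5)
  sc <- zscale(m, "column")$scaled
  expect_equal(colMeans(sc), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(sc, 2, sd), rep(1, 5), tolerance = 1e-12)
  # an already-standardized vector is untouched
  v <- as.numeric(scale(rnorm(10)))
  expect_equal(zscale(cbind(v, rnorm(10)))$scaled[, 1], v)
  cr <- zscale(rbind(c(3, 3, 3), c(1, 2, 4)), "row")
  expect_true(cr$constant[1])
  expect_identical(unname(cr$scaled[1, ]), c(0, 0, 0))
})

test_that("complete-linkage ordering matches an independent agglomeration", {
  expect_identical(hcluster_order(matrix(c(0, 10), 2, 1))$order, c(1L, 2L))
  # mutual distances 1, 5, 5: the close pair merges first at height 1
  tri <- matrix(c(0, 1, 5), 3, 1)
  hc <- hcluster_order(tri)
  expect_equal(hc$height[1], 1)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  set.seed(57)
  m <- matrix(rnorm(100), 20, 5)
  expect_equal(hcluster_order(m)$height, brute_complete_linkage_heights(m))
  expect_error(hcluster_order(matrix(c(1, NA), 1, 2)), "undefined")
})
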