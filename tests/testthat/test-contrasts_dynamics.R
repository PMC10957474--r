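# build a contrast_result directly with controlled posterior draws
make_cres <- function(delta_means, slope_case = NULL, slope_ctrl = NULL,
                      sd = 0.1, S = 500, seed = 1) {
  set.seed(seed)
  D <- nrow(delta_means)
  fid <- paste0("f", seq_len(D))
  delta <- array(rnorm(D * 4 * S, mean = rep(delta_means, S), sd = sd),
                 c(D, 4, S), dimnames = list(fid, paste0("T", 0:3), NULL))
  if (is.null(slope_case)) slope_case <- rep(0, D)
  if (is.null(slope_ctrl)) slope_ctrl <- rep(0, D)
  sc <- matrix(rnorm(D * S, slope_case, sd), D, S)
  st <- matrix(rnorm(D * S, slope_ctrl, sd), D, S)
  structure(list(name = "test", features = fid, visits = 0:3, delta = delta,
                 slope_case = sc, slope_ctrl = st,
                 levels = c(0.5, 0.9, 1),
                 summary = NULL),
            class = "contrast_result")
}

test_that("reference grids substitute fixed settings and frequency weights", {
  freqs <- c(pfs12 = 0.4, combo = 0.3, colitis = 0.2, ppi = 0.25)
  g5 <- build_reference_grid(freqs, "pfs12_mono")
  # case arm Z=1, all W=0: intercept weights pick beta0 + beta2 only
  expect_equal(which(g5$case$int != 0), c(1L, 3L))
  expect_equal(which(g5$case$slope != 0), c(2L, 4L))
  expect_equal(which(g5$ctrl$int != 0), 1L)

  # contrast 1 with all moderator frequencies zero reduces to contrast 5
  freqs0 <- c(pfs12 = 0.4, combo = 0, colitis = 0, ppi = 0)
  g1 <- build_reference_grid(freqs0, "pfs12")
  expect_equal(g1$case$int, g5$case$int)
  expect_equal(g1$ctrl$slope, g5$ctrl$slope)

  # averaged-over variables use observed sample frequencies
  meta <- make_meta(20, therapy = c("combo", "mono"), colitis = "no",
                    ppi = c("no", "no", "no", "yes"))
  expect_error(build_reference_grid(meta, "colitis"), "empty stratum")
  g <- build_reference_grid(meta, "pfs12")
  expect_equal(g$freqs[["combo"]], 0.5)
  expect_equal(g$case$int[5], 0.5)  # beta4 weighted by p(W1)
})

test_that("per-visit differences follow Delta(t) = Delta_int + t * Delta_slope", {
  set.seed(6)
  mean_focal <- matrix(0, 5, 16, dimnames = list(paste0("f", 1:5), NULL))
  mean_focal[1, 3] <- 1    # pfs12 intercept difference
  mean_focal[2, 4] <- 0.5  # visit:pfs12 slope difference
  draws <- make_clr_draws(mean_focal, S = 600, sd = 0.02, center = FALSE)
  grid <- build_reference_grid(c(pfs12 = 0.5, combo = 0, colitis = 0, ppi = 0),
                               "pfs12_mono")
  res <- contrast_posterior(draws, grid)
  sm <- res$summary
  # feature 1: stable intercept gap; feature 2: gap grows as 0.5 * t
  for (t in 0:3) {
    m1 <- sm$mean[sm$feature == "f1" & sm$visit == t]
    m2 <- sm$mean[sm$feature == "f2" & sm$visit == t]
    expect_equal(m1, 1, tolerance = 0.05)
    expect_equal(m2, 0.5 * t, tolerance = 0.05)
  }
  # Delta(0) equals the intercept difference exactly, draw by draw
  expect_equal(res$delta[, 1, ], res$intercept_diff, ignore_attr = TRUE)
  # credible intervals are nested across levels
  r1 <- sm[sm$feature == "f1" & sm$visit == 0, ]
  expect_true(r1$lo100 <= r1$lo90 && r1$lo90 <= r1$lo50)
  expect_true(r1$hi50 <= r1$hi90 && r1$hi90 <= r1$hi100)
})

test_that("a contrast of an arm with itself is exactly zero for every draw", {
  mean_focal <- matrix(rnorm(5 * 16), 5, 16,
                       dimnames = list(paste0("f", 1:5), NULL))
  draws <- make_clr_draws(mean_focal, S = 50)
  def <- list(case = list(Z = 1, W1 = 0, W2 = NA, W3 = NA),
              ctrl = list(Z = 1, W1 = 0, W2 = NA, W3 = NA))
  grid <- build_reference_grid(c(pfs12 = 0.5, combo = 0.3, colitis = 0.2,
                                 ppi = 0.1), def)
  res <- contrast_posterior(draws, grid)
  expect_true(all(res$delta == 0))
})

test_that("BCL significance uses equal-tailed interpolated quantiles", {
  # 96 of 100 positive draws with the 5% quantile above zero
  x <- c(-(4:1), seq(5, 100))
  expect_true(bcl_significant(x, 0.9))
  expect_false(bcl_significant(x, 0.95))
  expect_false(bcl_significant(x, 1))          # both signs present
  expect_true(bcl_significant(seq(0.1, 9, 0.1), 1))  # all positive
  set.seed(7)
  expect_false(bcl_significant(c(rnorm(500), -rnorm(500)), 0.5))
})

test_that("differential ranking sorts by posterior mean with stable ties", {
  mean_focal <- matrix(0, 3, 16,
                       dimnames = list(c("fb", "fa", "fc"), NULL))
  mean_focal[, 3] <- c(-0.2, 0.5, 0.5)
  draws <- make_clr_draws(mean_focal, S = 400, sd = 0.01)
  grid <- build_reference_grid(c(pfs12 = 0.5, combo = 0, colitis = 0, ppi = 0),
                               "pfs12_mono")
  res <- contrast_posterior(draws, grid)
  rk <- differential_ranking(res, 0)
  expect_equal(rk$feature[3], "fb")
  expect_true(rk$mean[1] >= rk$mean[2])

  # ranking invariant to adding a per-term constant to all clr coefficients
  draws2 <- draws
  draws2$Lambda <- draws2$Lambda + 0.37
  res2 <- contrast_posterior(draws2, grid)
  expect_equal(differential_ranking(res2, 0)$feature, rk$feature)
})

test_that("flag counts are monotonically non-increasing in BCL level", {
  set.seed(8)
  mean_focal <- matrix(0, 20, 16, dimnames = list(sprintf("f%02d", 1:20), NULL))
  mean_focal[, 3] <- rnorm(20, 0, 0.15)
  draws <- make_clr_draws(mean_focal, S = 400, sd = 0.1)
  grid <- build_reference_grid(c(pfs12 = 0.5, combo = 0, colitis = 0, ppi = 0),
                               "pfs12_mono")
  res <- contrast_posterior(draws, grid)
  counts <- bcl_flag_counts(res)
  expect_true(all(diff(counts) <= 0))
})

test_that("dynamics classifier reproduces the qualitative trajectory classes", {
  means <- rbind(
    stable  = c(1, 1, 1, 1),
    baseonly = c(1, 0, 0, 0),
    emergent = c(0, 0, 1, 2),
    crossing = c(-1, -0.3, 0.3, 1),
    none     = c(0, 0, 0, 0),
    caseflat = c(0, 0, 0, 0))
  cres <- make_cres(means,
                    slope_case = c(0, 0, 0, 0, 0, 0),
                    slope_ctrl = c(0, 0, 0, 0, 0, 1),
                    sd = 0.05, S = 600)
  lab <- classify_dynamics(cres, level = 0.9)
  expect_equal(lab$category[lab$feature == "f1"], "stable-difference")
  expect_equal(lab$category[lab$feature == "f2"], "baseline-only")
  expect_equal(lab$category[lab$feature == "f3"], "emergent")
  expect_equal(lab$category[lab$feature == "f4"], "crossing")
  expect_equal(lab$category[lab$feature == "f5"], "none")
  expect_equal(lab$category[lab$feature == "f6"], "case-flat")
})
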