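test_that("weighted-sum coding has frequency-weighted zero means", {
  # counts (60, 40), reference second: codes {+1, -1.5}
  f <- rep(c("x", "ref"), c(60, 40))
  cm <- encode_weighted_sum(factor(f, levels = c("x", "ref")))
  expect_equal(sort(unique(cm[, 1])), c(-1.5, 1))
  expect_equal(mean(cm[, 1]), 0, tolerance = 1e-12)

  # balanced binary reduces to classic sum contrasts
  cm2 <- encode_weighted_sum(rep(c("a", "b"), 50))
  expect_equal(sort(unique(cm2[, 1])), c(-1, 1))

  # 3-level factor, counts (2, 3, 5): reference row (-2/5, -3/5)
  f3 <- factor(rep(c("a", "b", "c"), c(2, 3, 5)))
  cm3 <- encode_weighted_sum(f3)
  expect_equal(unname(cm3[10, ]), c(-2 / 5, -3 / 5))
  expect_equal(colMeans(cm3), c(a = 0, b = 0), tolerance = 1e-12)

  expect_error(encode_weighted_sum(rep("only", 5)), "2 observed levels")
})

test_that("focal block expands the three-way interactions term by term", {
  meta <- make_meta(8)
  des <- suppressMessages(build_design(meta))
  expect_equal(ncol(des$X), 8L)
  expect_equal(des$spec$focal, 1:16)

  # sample at reference for everything, visit 0
  m1 <- make_meta(4, visit = c(0, 1, 2, 3), pfs12 = "<12")
  m1$prior_targeted <- c("no", "no", "yes", "yes")  # keep factors 2-level
  d1 <- suppressMessages(build_design(m1, include_patient = FALSE))
  expect_equal(unname(d1$X[1:16, 1]), c(1, rep(0, 15)))

  # visit 2, Z = 1, W1 = 1, W2 = W3 = 0: exactly beta0..beta7 = (1,2,1,2,1,2,1,2)
  m2 <- make_meta(4, visit = c(2, 0, 1, 3), pfs12 = c(">=12", "<12"),
                  therapy = c("combo", "mono"))
  d2 <- suppressMessages(build_design(m2, include_patient = FALSE))
  expect_equal(unname(d2$X[1:16, 1]),
               c(1, 2, 1, 2, 1, 2, 1, 2, rep(0, 8)))
})

test_that("peripheral rows are centered and term_index resolves aliases", {
  meta <- make_meta(12)
  des <- suppressMessages(build_design(meta))
  periph <- des$X[-(1:16), , drop = FALSE]
  expect_true(all(abs(rowMeans(periph)) < 1e-9))
  expect_equal(term_index(des$spec, "beta0"), 1L)
  expect_equal(term_index(des$spec, "beta15"), 16L)
  expect_equal(term_index(des$spec, "visit:pfs12"), 4L)
  expect_equal(term_index(des$spec, "age"),
               which(des$spec$term_names == "age"))
  expect_error(term_index(des$spec, "nonsense"), "unknown term")
})

test_that("intercept/slope decomposition equals direct evaluation of the model", {
  # evaluating (intercepts) + (slopes) * X must equal beta' x column-wise
  set.seed(5)
  meta <- make_meta(16, therapy = c("mono", "combo"),
                    colitis = c("no", "no", "yes"), ppi = c("no", "yes"))
  des <- suppressMessages(build_design(meta, include_patient = FALSE))
  beta <- rnorm(16)
  direct <- drop(beta %*% des$X[1:16, ])
  Z <- as.numeric(meta$pfs12 == ">=12")
  W1 <- as.numeric(meta$therapy == "combo")
  W2 <- as.numeric(meta$colitis == "yes")
  W3 <- as.numeric(meta$ppi == "yes")
  icpt <- beta[1] + beta[3] * Z + beta[5] * W1 + beta[7] * Z * W1 +
    beta[9] * W2 + beta[11] * Z * W2 + beta[13] * W3 + beta[15] * Z * W3
  slp <- beta[2] + beta[4] * Z + beta[6] * W1 + beta[8] * Z * W1 +
    beta[10] * W2 + beta[12] * Z * W2 + beta[14] * W3 + beta[16] * Z * W3
  expect_equal(icpt + slp * meta$visit, unname(direct), tolerance = 1e-12)
})

test_that("missing metadata fields are reported by sample and field", {
  meta <- make_meta(6)
  meta$bmi[3] <- NA
  expect_error(suppressMessages(build_design(meta)), "bmi.*S3")
})
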