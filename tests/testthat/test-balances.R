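test_that("balance scores evaluate the geometric-mean log ratio", {
  v <- matrix(c(0.4, 0.1, 0.2, 0.3), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "S1"))
  tab <- abundance_table(v, "SGB")
  b <- balance_score(tab, balance_def("a", c("b", "c")))
  expect_equal(unname(b), 1.5 * log(2), tolerance = 1e-12)

  # identical sets on both sides give zero... by disjointness they cannot;
  # a feature against itself duplicated is rejected instead
  expect_error(balance_def("a", "a"), "overlap")

  # scale invariance: multiplying a sample by a constant leaves B unchanged
  v2 <- v * 7
  tab2 <- abundance_table(v2, "SGB")
  expect_equal(balance_score(tab2, balance_def("a", c("b", "c"))), b)
})

test_that("balances are subcompositionally coherent", {
  tab <- make_tab(D = 8, n = 10, seed = 2)
  def <- balance_def(c("f1", "f2"), c("f5", "f6", "f7"))
  b_full <- balance_score(tab, def)
  sub <- abundance_table(renormalize(abundance_table(
    tab$values[c("f1", "f2", "f5", "f6", "f7", "f8"), ], "SGB"))$values, "SGB")
  expect_equal(balance_score(sub, def), b_full, tolerance = 1e-12)
})

test_that("missing balance members error, or drop with a warning on request", {
  tab <- make_tab(D = 4, n = 3)
  def <- balance_def(c("f1", "nope"), c("f3"))
  expect_error(balance_score(tab, def), "nope")
  expect_warning(b <- balance_score(tab, def, drop_missing = TRUE), "nope")
  expect_equal(b, balance_score(tab, balance_def("f1", "f3")))
})

test_that("median stratification sends ties and the median element Low", {
  expect_equal(as.character(median_stratify(c(1, 2, 3, 4))),
               c("Low", "Low", "High", "High"))
  expect_true(all(median_stratify(rep(2, 5)) == "Low"))
  expect_equal(as.character(median_stratify(c(1, 2, 3))),
               c("Low", "Low", "High"))
})

test_that("rank AUC counts concordant pairs with midrank ties", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auc_rank(1:10, rep(c(0, 1), each = 5)), 1)
  expect_equal(auc_rank(10:1, rep(c(0, 1), each = 5)), 0)
  expect_equal(auc_rank(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
})

test_that("rank AUC equals AUC of any monotone transform (logistic score)", {
  set.seed(12)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(1.5 * x))
  if (length(unique(y)) == 2L) {
    fit <- glm(y ~ x, family = binomial())
    s <- unname(sign(coef(fit)[2]))
    expect_equal(auc_rank(fitted(fit), y), auc_rank(x, y) * s + (s < 0),
                 tolerance = 1e-12)
  }
})

test_that("cross-validated AUC behaves at the extremes and under the null", {
  # perfect separation
  sc <- c(rnorm(40, -4), rnorm(40, 4))
  y <- rep(c(0, 1), each = 40)
  cv <- cv_auc(sc, y, repeats = 10, folds = 5, seed = 1)
  expect_equal(cv$mean, 1.0, tolerance = 1e-9)
  expect_equal(cv$sd, 0.0, tolerance = 1e-9)

  # label-independent scores at n = 200: mean AUC within 0.5 +/- 0.1
  set.seed(13)
  sc0 <- rnorm(200)
  y0 <- rep(c(0, 1), each = 100)
  cv0 <- cv_auc(sc0, y0, repeats = 25, folds = 5, seed = 2)
  expect_lt(abs(cv0$mean - 0.5), 0.1)
})

test_that("external evaluation equals the unsplit fold model", {
  tab <- make_tab(D = 6, n = 40, seed = 3)
  def <- balance_def(c("f1", "f2"), c("f4", "f5"))
  b <- balance_score(tab, def)
  set.seed(14)
  y <- rbinom(40, 1, plogis(2 * scale(b)))
  if (length(unique(y)) == 2L) {
    ev <- external_eval(tab, def, y)
    expect_equal(ev$auc, auc_rank(fitted(glm(y ~ b, family = binomial())), y))
    # monotone-transform invariance links it back to the raw balance
    expect_equal(ev$auc, max(auc_rank(b, y), 1 - auc_rank(b, y)))
  }
})
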