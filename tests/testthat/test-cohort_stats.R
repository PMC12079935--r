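test_that("spearman_matrix matches identities and the rank-Pearson oracle", {
  tab <- simulate_cohort(50, seed = 3)
  cols <- c("nhop_max", "suv_max", "mtv_ml")
  sp <- spearman_matrix(tab, cols)
  expect_equal(unname(diag(sp$r)), rep(1, 3))
  expect_equal(sp$r, t(sp$r))

  tab$neg <- -tab$nhop_max
  sp2 <- spearman_matrix(tab, c("nhop_max", "neg"))
  expect_equal(sp2$r["nhop_max", "neg"], -1)

  set.seed(8)
  small <- data.frame(a = rnorm(10), b = sample(1:5, 10, TRUE), c = runif(10))
  sp3 <- spearman_matrix(small, c("a", "b", "c"))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(sp3$r[pair[1], pair[2]],
                 brute_spearman(small[[pair[1]]], small[[pair[2]]]),
                 tolerance = 1e-12)
  # p-value via the t approximation
  r <- sp3$r["a", "c"]; n <- 10
  expect_equal(sp3$p["a", "c"],
               2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))

  small$k <- 1
  expect_warning(sp4 <- spearman_matrix(small, c("a", "k")), "constant")
  expect_true(is.na(sp4$r["a", "k"]))
})

test_that("roc_youden handles separation, the 4-point example and ties", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), n_boot = 50)
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)

  r2 <- roc_youden(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(r2$auc, 0.75)

  r3 <- roc_youden(rep(2.5, 8), rep(c(0, 1), 4), n_boot = 0)
  expect_equal(r3$auc, 0.5)

  expect_error(roc_youden(1:4, c(1, 1, 1, 1), 10), "single-class")
})

test_that("AUC is concordance-symmetric and monotone-invariant", {
  set.seed(12)
  for (rep in 1:5) {
    sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    a1 <- roc_youden(sc, lb, n_boot = 0)$auc
    a2 <- roc_youden(-sc, lb, n_boot = 0)$auc
    expect_equal(a1, a2)                       # auto-orientation symmetry
    expect_equal(brute_auc(sc, lb) + brute_auc(-sc, lb), 1)
    a3 <- roc_youden(exp(sc), lb, n_boot = 0)$auc
    expect_equal(a1, a3, tolerance = 1e-12)    # strictly monotone transform
  }
})

test_that("Youden cutoff equals the exhaustive oracle with attained sens/spec", {
  set.seed(23)
  for (rep in 1:10) {
    sc <- round(rnorm(80), 1)                  # force ties
    lb <- rbinom(80, 1, 0.35)
    if (length(unique(lb)) < 2) next
    r <- roc_youden(sc, lb, n_boot = 0)
    o <- brute_youden(sc, lb, r$orientation)
    expect_equal(r$cutoff, unname(o["cutoff"]))
    expect_equal(r$sensitivity, unname(o["sens"]))
    expect_equal(r$specificity, unname(o["spec"]))
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
})

test_that("logistic_fit reproduces the 2x2 cross-product odds ratio", {
  tab <- data.frame(y = rep(c(1, 0, 1, 0), c(20, 80, 10, 90)),
                    x = rep(c(1, 1, 0, 0), c(20, 80, 10, 90)))
  f <- logistic_fit(tab, "y", "x", mode = "univariate")
  expect_equal(f$ratio, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(f$ratio, exp(f$estimate))
  expect_true(f$p_value > 0 && f$p_value <= 1)
})

test_that("logistic_fit recovers null and nonnull coefficients", {
  set.seed(14)
  n <- 2000
  x_null <- rnorm(n); y <- rbinom(n, 1, 0.3)
  f <- logistic_fit(data.frame(y = y, x = x_null), "y", "x")
  expect_true(f$ci_low <= 1 && 1 <= f$ci_high)

  x <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(-0.5 - 1.0 * x))
  f2 <- logistic_fit(data.frame(y = y2, x = x), "y", "x")
  expect_lt(abs(f2$estimate - (-1.0)), 3 * f2$se)

  expect_error(logistic_fit(data.frame(y = y, x = 1), "y", "x"), "constant")
  expect_error(logistic_fit(data.frame(y = rep(1, 20), x = rnorm(20)), "y", "x"),
               "both classes")
})

test_that("logistic_fit flags complete separation instead of reporting silently", {
  tab <- data.frame(y = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, 0), rnorm(20, 30)))
  f <- logistic_fit(tab, "y", "x")
  expect_false(attr(f, "converged"))
})

test_that("multivariate mode fits jointly", {
  tab <- simulate_cohort(800, seed = 21)
  f <- logistic_fit(tab, "recurrence", c("nhop_max", "suv_max"),
                    mode = "multivariate")
  expect_equal(nrow(f), 2)
  expect_identical(attr(f, "mode"), "multivariate")
  fu <- logistic_fit(tab, "recurrence", c("nhop_max", "suv_max"),
                     mode = "univariate")
  expect_equal(nrow(fu), 2)
  expect_false(isTRUE(all.equal(f$estimate, fu$estimate)))
})

test_that("cox_fit matches a brute-force partial-likelihood maximization", {
  toy <- data.frame(t = c(1, 2, 3), e = c(1, 1, 1), x = c(1, 0, 1))
  f <- cox_fit(toy, "t", "e", "x")
  brute <- optimize(function(b) brute_cox_loglik(b, toy$t, toy$e, toy$x),
                    c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(f$estimate, brute, tolerance = 1e-6)
  expect_equal(f$ratio, exp(f$estimate))
})

test_that("cox_fit recovers null hazards and validates inputs", {
  set.seed(15)
  n <- 2000
  tab <- data.frame(t = rexp(n, 0.05), e = rbinom(n, 1, 0.8), x = rnorm(n))
  f <- cox_fit(tab, "t", "e", "x")
  expect_true(f$ci_low <= 1 && 1 <= f$ci_high)
  expect_error(cox_fit(data.frame(t = c(1, 2), e = c(0, 0), x = c(1, 2)),
                       "t", "e", "x"), "no events")
  expect_error(cox_fit(data.frame(t = c(-1, 2), e = c(1, 0), x = c(1, 2)),
                       "t", "e", "x"), "> 0")
})

test_that("km_logrank matches hand-tabulated risk sets and trivial identity", {
  # identical data as both groups
  d <- data.frame(t = c(3, 5, 7, 9), e = c(1, 0, 1, 1))
  both <- rbind(cbind(d, g = "A"), cbind(d, g = "B"))
  km <- km_logrank(both, "t", "e", "g")
  expect_equal(km$logrank_chi2, 0)
  expect_equal(km$logrank_p, 1)

  # 6-subject toy with hand-enumerable risk sets
  toy <- data.frame(t = c(1, 2, 3, 4, 5, 6), e = c(1, 1, 0, 1, 1, 1),
                    g = c("A", "B", "A", "B", "A", "B"))
  km2 <- km_logrank(toy, "t", "e", "g")
  expect_equal(km2$logrank_chi2, brute_logrank(toy$t, toy$e, toy$g),
               tolerance = 1e-9)
  expect_equal(km2$logrank_p,
               pchisq(km2$logrank_chi2, 1, lower.tail = FALSE))

  # survival curves: start at risk n, non-increasing; equal to the empirical
  # survival function when there is no censoring
  nc <- data.frame(t = c(2, 4, 4, 7, 9), e = 1, g = "A")
  nc2 <- rbind(nc, data.frame(t = c(1, 3, 8), e = 1, g = "B"))
  km3 <- km_logrank(nc2, "t", "e", "g")
  cA <- km3$curves[km3$curves$group == "A", ]
  expect_equal(cA$survival, sapply(cA$time, function(x) mean(nc$t > x)))
  expect_true(all(diff(cA$survival) <= 1e-12))

  expect_error(km_logrank(data.frame(t = 1:3, e = 1, g = "A"), "t", "e", "g"),
               ">= 2")
})

test_that("dichotomize splits at the cutoff with equal values grouped low", {
  tab <- data.frame(x = c(0.2, 0.43, 0.5, 0.9))
  g <- dichotomize(tab, "x", 0.43)
  expect_identical(as.character(g$group), c("low", "low", "high", "high"))

  expect_warning(dichotomize(tab, "x", 10), "one side")
  tab2 <- data.frame(x = runif(101))
  g2 <- dichotomize(tab2, "x", median(tab2$x))
  expect_equal(sum(g2$group == "low"), 51)   # median grouped low

  set.seed(33)
  v <- runif(200)
  g3 <- dichotomize(data.frame(x = v), "x", 0.43)
  expect_equal(sum(g3$group == "high"), sum(v > 0.43))
})

test_that("build_report renders the frozen schemas", {
  tab <- simulate_cohort(300, seed = 2)
  roc <- list(nhop_max = roc_youden(tab$nhop_max, tab$recurrence, n_boot = 20))
  rep0 <- build_report(roc = roc)
  expect_identical(names(rep0$roc),
                   c("parameter", "auc", "ci_low", "ci_high", "sensitivity",
                     "specificity", "cutoff"))
  expect_equal(nrow(rep0$roc), 1)

  fu <- logistic_fit(tab, "recurrence", c("nhop_max", "suv_max"))
  fm <- logistic_fit(tab, "recurrence", "nhop_max", mode = "multivariate")
  rep1 <- build_report(fits_uni = fu, fits_multi = fm)
  expect_identical(names(rep1$regression),
                   c("parameter", "p_uni", "ratio_uni", "ci_low_uni",
                     "ci_high_uni", "p_multi", "ratio_multi", "ci_low_multi",
                     "ci_high_multi"))
  # predictors absent from the multivariate fit are blank, not zero
  expect_true(is.na(rep1$regression$ratio_multi[rep1$regression$parameter == "suv_max"]))
  expect_error(build_report(), "at least one")
})

test_that("null CI coverage is nominal for both regressions", {
  cover_lg <- cover_cx <- 0
  n_sim <- 50
  for (s in 1:n_sim) {
    set.seed(1000 + s)
    n <- 150
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    f <- logistic_fit(data.frame(y = y, x = x), "y", "x")
    cover_lg <- cover_lg + (f$ci_low <= 1 && 1 <= f$ci_high)
    t0 <- rexp(n, 0.1); e0 <- rbinom(n, 1, 0.8)
    fc <- cox_fit(data.frame(t = t0, e = e0, x = x), "t", "e", "x")
    cover_cx <- cover_cx + (fc$ci_low <= 1 && 1 <= fc$ci_high)
  }
  expect_gte(cover_lg, 43)   # 95% nominal, binomial 3-sigma lower bound
  expect_gte(cover_cx, 43)
})
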