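random_table <- function() {
  stats::setNames(as.integer(sample(1:200, 4, replace = TRUE)),
                  c("a", "b", "c", "d"))
}

table_to_df <- function(t) {
  data.frame(
    x = rep(c(1L, 1L, 0L, 0L), t),
    y = rep(c(1L, 0L, 1L, 0L), t))
}

test_that("contingency counts the four joint outcomes", {
  co <- make_cohort(data.frame(X = c(1L, 1L, 0L, 0L),
                               Y = c(1L, 0L, 1L, 0L)))
  expect_equal(contingency(co, "X", "Y"),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(unname(contingency(co, "X", "X")[c("b", "c")]), c(0L, 0L))
  t0 <- contingency(make_cohort(data.frame(X = integer(0),
                                           Y = integer(0))), "X", "Y")
  expect_equal(unname(t0), rep(0L, 4))
  expect_error(contingency(co, "X", "nope"), "unknown column")
  # symmetric under pair swap up to b <-> c
  t1 <- contingency(co, "X", "Y"); t2 <- contingency(co, "Y", "X")
  expect_equal(t1[["a"]], t2[["a"]])
  expect_equal(t1[["b"]], t2[["c"]])
})

test_that("chi2_yates matches formula, boundaries and degeneracy", {
  r <- chi2_yates(c(a = 10L, b = 20L, c = 30L, d = 40L))
  expect_equal(r$statistic, 0.4464286, tolerance = 1e-6)
  expect_equal(r$p_value, 0.5040358, tolerance = 1e-6)

  prop <- chi2_yates(c(a = 10L, b = 20L, c = 20L, d = 40L)) # ad = bc
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  strong <- chi2_yates(c(a = 50L, b = 0L, c = 0L, d = 50L))
  expect_equal(strong$statistic, 96.04, tolerance = 1e-10)
  expect_lt(strong$p_value, 1e-15)

  degen <- chi2_yates(c(a = 0L, b = 0L, c = 3L, d = 7L))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("OR, RR, phi reproduce worked values and zero-cell handling", {
  t <- c(a = 10L, b = 20L, c = 30L, d = 40L)
  or <- odds_ratio_ci(t)
  expect_equal(or$or, 2 / 3, tolerance = 1e-12)
  expect_equal(or$ci, c(0.27249, 1.63104), tolerance = 1e-4)
  expect_false(or$corrected)

  sym <- odds_ratio_ci(c(a = 10L, b = 10L, c = 10L, d = 10L))
  expect_equal(sym$or, 1)
  expect_lt(sym$ci[1], 1); expect_gt(sym$ci[2], 1)

  corr <- odds_ratio_ci(c(a = 5L, b = 0L, c = 3L, d = 7L))
  expect_true(corr$corrected)
  expect_true(is.finite(corr$or) && corr$or > 0)

  expect_equal(risk_ratio_ci(t)$rr, 0.7777778, tolerance = 1e-6)
  expect_equal(risk_ratio_ci(c(a = 10L, b = 20L, c = 10L, d = 20L))$rr, 1)

  expect_equal(phi_coefficient(t), -0.08909, tolerance = 1e-4)
  expect_equal(phi_coefficient(c(a = 50L, b = 0L, c = 0L, d = 50L)), 1)
  expect_equal(phi_coefficient(c(a = 10L, b = 20L, c = 20L, d = 40L)), 0)
  expect_true(is.na(phi_coefficient(c(a = 0L, b = 0L, c = 5L, d = 5L))))
})

test_that("statistics agree with independent reference routes", {
  # dual-route check on random tables: chisq.test, logit-glm, log-glm, cor
  set.seed(101)
  for (rep in 1:60) {
    t <- random_table()
    ref <- suppressWarnings(stats::chisq.test(
      matrix(t, 2, 2, byrow = TRUE), correct = TRUE))
    mine <- chi2_yates(t)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)

    df <- data.frame(y = c(1L, 0L, 1L, 0L), x = c(1L, 1L, 0L, 0L),
                     w = as.numeric(t))
    mle <- c(qlogis(t[["c"]] / (t[["c"]] + t[["d"]])),
             log(t[["a"]] * t[["d"]] / (t[["b"]] * t[["c"]])))
    fit <- suppressWarnings(glm(y ~ x, weights = w, data = df,
                                family = binomial(), start = mle,
                                control = list(epsilon = 1e-14,
                                               maxit = 200)))
    expect_equal(odds_ratio_ci(t)$or, unname(exp(coef(fit)["x"])),
                 tolerance = 1e-8)
    expect_equal(log(odds_ratio_ci(t)$ci[2] / odds_ratio_ci(t)$or) / 1.96,
                 unname(summary(fit)$coefficients["x", 2]),
                 tolerance = 1e-6)

    expanded <- table_to_df(t)
    expect_equal(phi_coefficient(t), cor(expanded$x, expanded$y),
                 tolerance = 1e-8)

    st <- c(log(t[["c"]] / (t[["c"]] + t[["d"]])),
            log((t[["a"]] / (t[["a"]] + t[["b"]])) /
                  (t[["c"]] / (t[["c"]] + t[["d"]]))))
    rrfit <- suppressWarnings(glm(y ~ x, weights = w, data = df,
                                  family = binomial(link = "log"),
                                  start = st))
    expect_equal(risk_ratio_ci(t)$rr, unname(exp(coef(rrfit)["x"])),
                 tolerance = 1e-6)
  }
})

test_that("bonferroni flags follow alpha/m and are monotone in alpha", {
  expect_true(bonferroni_adjust(0.04))
  expect_true(bonferroni_adjust(rep(0.0004, 100))[1])  # 0.0004 < 0.0005
  expect_false(bonferroni_adjust(rep(0.0006, 100))[1])
  expect_length(bonferroni_adjust(numeric(0)), 0L)
  set.seed(5)
  p <- runif(200)
  f1 <- bonferroni_adjust(p, alpha = 0.05)
  f2 <- bonferroni_adjust(p, alpha = 0.01)
  expect_true(all(f1[f2])) # lowering alpha never adds a significant pair
})

test_that("parametric-association transform follows the batch rule", {
  p <- c(1e-8, 1e-4, 0.05)
  s <- transform_parametric_association(p)
  expect_equal(attr(s, "ld_star"), 8)
  expect_equal(as.numeric(s), c(8 / 9, 4 / 9, -log10(0.05) / 9),
               tolerance = 1e-10)
  expect_equal(as.numeric(transform_parametric_association(c(0, 0.5)))[1], 1)
  expect_equal(as.numeric(transform_parametric_association(c(1, 0.5)))[1], 0)
  # strictly decreasing in p; range [0, 1]; batch max attained
  set.seed(6)
  batch <- sort(10^runif(50, -12, 0))
  sc <- as.numeric(transform_parametric_association(batch))
  expect_true(all(diff(sc) < 0))
  expect_true(all(sc >= 0 & sc <= 1))
  # without an exact zero the batch maximum is ld*/(ld* + 1), strictly
  # below the T(0) = 1 ceiling
  ld <- attr(transform_parametric_association(batch), "ld_star")
  expect_equal(max(sc), ld / (ld + 1))
  expect_equal(max(as.numeric(transform_parametric_association(
    c(batch, 0)))), 1)
})

test_that("OR/RR transforms obey symmetry, range and ignore rules", {
  tr <- transform_or(c(4, 0.5, 150))
  expect_equal(tr$star, 4)
  expect_equal(tr$score[1:2], c(1, 0.5))
  expect_true(tr$ignored[3] && is.na(tr$score[3]))

  rr <- transform_rr(c(2, 10))
  expect_equal(rr$score, c(0.2, 1))
  expect_equal(transform_rr(c(1, 10))$score[1], 0.1) # RR = 1 -> 1/RR*
  expect_true(transform_rr(c(0.005, 2))$ignored[1])

  set.seed(7)
  x <- exp(runif(40, -4, 4))
  a <- transform_or(c(x, 1 / x))
  expect_equal(a$score[seq_along(x)], a$score[length(x) + seq_along(x)],
               tolerance = 1e-12) # T(x) = T(1/x)
  expect_true(all(a$score >= 0 & a$score <= 1, na.rm = TRUE))
  expect_equal(max(a$score, na.rm = TRUE), 1)
})

test_that("pairwise_table assembles all statistics coherently", {
  bn <- chain_bn(3, prevalence = 0.15, effect = 2)
  co <- simulate_cohort(bn, 5000, seed = 17)
  pw <- pairwise_table(co)
  expect_equal(nrow(pw), 3L)
  expect_equal(attr(pw, "m"), 3L)
  expect_true(all(pw$chi2_p >= 0 & pw$chi2_p <= 1))
  expect_true(all(pw$t_chi2 >= 0 & pw$t_chi2 <= 1))
  ld <- attr(pw, "ld_star")
  expect_equal(max(pw$t_chi2),
               if (any(pw$chi2_p == 0)) 1 else ld / (ld + 1))
  expect_true(pw$bonferroni[pw$var1 == "D01" & pw$var2 == "D02"])
  # round-trip through the TSV writer
  path <- tempfile(fileext = ".tsv")
  write_pairwise_tsv(pw, path)
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$chi2_p, pw$chi2_p, tolerance = 1e-10)
})

test_that("logistic_fit recovers truth and flags pathologies", {
  set.seed(23)
  n <- 50000
  x <- as.integer(runif(n) < 0.3)
  y_null <- as.integer(runif(n) < 0.1)
  co <- make_cohort(data.frame(Y = y_null, X = x))
  fit <- logistic_fit(co, "Y", "X")
  z <- fit$estimate[fit$term == "X"] / fit$std_error[fit$term == "X"]
  expect_lt(abs(z), 3)

  # recovery: logit P(y) = -2 + 1 * x, 100 replicates, coverage >= 90%
  cover <- 0L
  for (r in 1:100) {
    xr <- as.integer(runif(n / 10) < 0.4)
    yr <- as.integer(runif(n / 10) < plogis(-2 + xr))
    f <- logistic_fit(make_cohort(data.frame(Y = yr, X = xr)), "Y", "X")
    est <- f$estimate[f$term == "X"]; se <- f$std_error[f$term == "X"]
    if (abs(est - 1) < 1.96 * se) cover <- cover + 1L
  }
  expect_gte(cover, 90L)

  co_const <- make_cohort(data.frame(Y = y_null[1:100], Z = rep(0L, 100),
                                     X = x[1:100]))
  expect_warning(f2 <- logistic_fit(co_const, "Y", c("X", "Z")),
                 "constant predictor")
  expect_false("Z" %in% f2$term)

  sep <- make_cohort(data.frame(Y = c(rep(1L, 30), rep(0L, 30)),
                                X = c(rep(1L, 30), rep(0L, 30))))
  expect_warning(f3 <- logistic_fit(sep, "Y", "X"), "separation")
  expect_true(attr(f3, "separation"))
})

test_that("ward_clustering separates blocks and validates input", {
  m <- matrix(0.9, 6, 6)
  m[1:3, 1:3] <- 1e-9
  m[4:6, 4:6] <- 1e-9
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("d", 1:6)
  hc <- ward_clustering(m)
  expect_equal(sort(unname(stats::cutree(hc, 2)[1:3])), rep(1L, 3))
  expect_equal(length(unique(stats::cutree(hc, 2)[4:6])), 1L)

  two <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  hc2 <- ward_clustering(two)
  expect_equal(hc2$height, 0.3)

  dup <- matrix(c(0, 0, 0.5,
                  0, 0, 0.5,
                  0.5, 0.5, 0), 3, 3, byrow = TRUE)
  hc3 <- ward_clustering(dup)
  expect_equal(hc3$height[1], 0) # identical rows merge first at 0

  expect_error(ward_clustering(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  nw <- ward_newick(hc)
  expect_match(nw, "^\\(.*\\);$")
  if (requireNamespace("ape", quietly = TRUE)) {
    tr <- ape::read.tree(text = nw)
    expect_setequal(tr$tip.label, paste0("d", 1:6))
  }
})
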