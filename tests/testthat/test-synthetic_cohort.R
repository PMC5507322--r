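test_that("sample_random_dag respects density, caps and determinism", {
  expect_length(dag_edges(sample_random_dag(
    simulation_spec(n_nodes = 1, edge_density = 0.5, max_parents = 2)))$from,
    0L)

  full <- sample_random_dag(
    simulation_spec(n_nodes = 3, edge_density = 1, max_parents = 2))
  expect_equal(nrow(dag_edges(full)), 3L)
  expect_false(is.null(topo_sort(full)))

  s <- simulation_spec(n_nodes = 20, edge_density = 0.1, seed = 42)
  expect_identical(sample_random_dag(s), sample_random_dag(s))

  d20 <- sample_random_dag(simulation_spec(n_nodes = 20, edge_density = 0.15,
                                           max_parents = 3, seed = 7))
  expect_true(all(vapply(d20$parents, length, 1L) <= 3L))

  expect_error(sample_random_dag(
    simulation_spec(n_nodes = 10, edge_density = 0.9, max_parents = 2)),
    "configuration error")
})

test_that("expected edge count tracks edge_density", {
  counts <- vapply(1:30, function(s) nrow(dag_edges(sample_random_dag(
    simulation_spec(n_nodes = 15, edge_density = 0.05, max_parents = 4,
                    seed = s)))), 1L)
  expect_gt(mean(counts), 0.05 * 15 * 14 / 2 * 0.6)
  expect_lt(mean(counts), 0.05 * 15 * 14 / 2 * 1.4)
})

test_that("sample_cpts hits prevalence targets and effect ranges", {
  spec0 <- simulation_spec(n_nodes = 5, edge_density = 0,
                           prevalence_range = c(0.05, 0.05),
                           confounder_fraction = 0, seed = 3)
  bn0 <- sample_cpts(sample_random_dag(spec0), spec0)
  expect_equal(unname(bn0$beta0[paste0("D0", 1:5)]),
               rep(qlogis(0.05), 5), tolerance = 1e-12)

  spec_z <- simulation_spec(n_nodes = 6, edge_density = 0.3,
                            effect_range = c(0, 0),
                            confounder_fraction = 0, max_parents = 4,
                            seed = 5)
  bn_z <- sample_cpts(sample_random_dag(spec_z), spec_z)
  expect_true(all(abs(unlist(bn_z$beta)) == 0))

  spec_s <- simulation_spec(n_nodes = 2, edge_density = 1, max_parents = 1,
                            effect_range = c(2, 2),
                            prevalence_range = c(0.1, 0.1),
                            confounder_fraction = 0, seed = 9)
  bn_s <- sample_cpts(sample_random_dag(spec_s), spec_s)
  b <- unlist(bn_s$beta)
  b <- b[abs(b) > 0]
  expect_equal(unname(abs(b)), 2)
  co <- simulate_cohort(bn_s, n_subjects = 50000, seed = 11)
  child <- names(which(vapply(bn_s$beta, function(x) any(x != 0), TRUE)))
  parent <- names(bn_s$beta[[child]])
  p1 <- mean(co$data[[child]][co$data[[parent]] == 1])
  p0 <- mean(co$data[[child]][co$data[[parent]] == 0])
  if (b > 0) expect_gt(p1, p0) else expect_lt(p1, p0)
})

test_that("simulate_cohort: marginals, monotonicity, determinism", {
  single <- ground_truth_bn(dag(c("D1", "sex", "age")),
                            c(D1 = 0.5))
  co <- simulate_cohort(single, n_subjects = 100000, seed = 2)
  expect_equal(mean(co$data$D1), 0.5, tolerance = 0.01)

  bn <- chain_bn(2, prevalence = 0.2, effect = 3)
  co2 <- simulate_cohort(bn, n_subjects = 20000, seed = 4)
  expect_gt(mean(co2$data$D02[co2$data$D01 == 1]),
            mean(co2$data$D02[co2$data$D01 == 0]))

  expect_identical(simulate_cohort(bn, 1000, seed = 8),
                   simulate_cohort(bn, 1000, seed = 8))
})

test_that("simulated prevalences match a 10x forward-sampling oracle", {
  spec <- simulation_spec(n_nodes = 12, n_subjects = 2000,
                          edge_density = 0.12, max_parents = 3,
                          prevalence_range = c(0.05, 0.3),
                          confounder_fraction = 0.3, seed = 21)
  bn <- sample_cpts(sample_random_dag(spec), spec)
  co <- simulate_cohort(bn, spec$n_subjects, seed = 21)
  oracle <- simulate_cohort(bn, spec$n_subjects * 10, seed = 900)
  for (d in cohort_diseases(co)) {
    p_hat <- mean(co$data[[d]])
    p_ref <- mean(oracle$data[[d]])
    se <- sqrt(p_ref * (1 - p_ref) * (1 / spec$n_subjects +
                                        1 / (10 * spec$n_subjects)))
    expect_lt(abs(p_hat - p_ref), 3 * se + 1e-9)
  }
})

test_that("d-separated pairs have vanishing stratified association", {
  # two diseases confounded only by sex: d-separated given {sex, age}
  d <- dag(c("A", "B", "sex", "age"),
           list(A = "sex", B = "sex"))
  bn <- ground_truth_bn(d, c(A = 0.2, B = 0.2),
                        list(A = c(sex = 1.5), B = c(sex = 1.5)))
  co <- simulate_cohort(bn, 40000, seed = 31)
  phis <- vapply(0:1, function(s) {
    sub <- make_cohort(co$data[co$data$sex == s, ])
    abs(phi_coefficient(contingency(sub, "A", "B")))
  }, 1.0)
  expect_true(all(phis < 0.02))          # -> 0 within strata
  marg <- phi_coefficient(contingency(co, "A", "B"))
  expect_gt(marg, 0.02)                  # confounded marginally

  bn2 <- chain_bn(2, prevalence = 0.2, effect = 2)
  co2 <- simulate_cohort(bn2, 40000, seed = 32)
  expect_gt(abs(phi_coefficient(contingency(co2, "D01", "D02"))), 0.05)
})

test_that("simulate_onsets: support, forced ordering, order fraction", {
  bn <- chain_bn(2, prevalence = 0.5, effect = 1, seed = 13)
  co <- simulate_cohort(bn, 40000, seed = 13)
  co1 <- simulate_onsets(co, bn, seed = 13, p_order = 1)
  expect_true(all(is.na(co1$onset[co1$data$D01 == 0L, "D01"])))
  aff <- co1$data$D01 == 1L
  expect_true(all(!is.na(co1$onset[aff, "D01"])))
  expect_true(all(co1$onset[aff, "D01"] >= 10))
  expect_true(all(co1$onset[aff, "D01"] <= co1$age_years[aff] + 1e-9))

  both <- co1$data$D01 == 1L & co1$data$D02 == 1L
  expect_gt(sum(both), 10000)
  expect_true(all(co1$onset[both, "D01"] < co1$onset[both, "D02"]))

  co8 <- simulate_onsets(co, bn, seed = 14, p_order = 0.8)
  frac <- mean(co8$onset[both, "D01"] < co8$onset[both, "D02"])
  expect_equal(frac, 0.8, tolerance = 0.02 / 0.8) # 0.8 +/- 0.02
})

test_that("filter_onset_before implements the stated rules", {
  onset <- matrix(c(40, 50,
                    40, 30,
                    40, NA,
                    NA, 35), byrow = TRUE, ncol = 2,
                  dimnames = list(NULL, c("T", "X")))
  df <- data.frame(T = c(1L, 1L, 1L, 0L), X = c(1L, 1L, 1L, 1L))
  co <- make_cohort(df, onset = onset)

  f <- filter_onset_before(co, "T", keep_missing_onset = TRUE)
  expect_equal(f$data$X, c(0L, 1L, 1L, 1L)) # after -> dropped; before,
                                            # missing, non-target -> kept
  expect_true(is.na(f$onset[1, "X"]))

  f2 <- filter_onset_before(co, "T", keep_missing_onset = FALSE)
  expect_equal(f2$data$X, c(0L, 1L, 0L, 1L))

  # idempotent, never increases counts
  expect_identical(filter_onset_before(f, "T"), f)
  expect_true(all(colSums(f$data) <= colSums(co$data)))

  co_noonset <- make_cohort(df)
  expect_error(filter_onset_before(co_noonset, "T"), "onset")
  expect_error(filter_onset_before(co, "missing"), "unknown target")
})

test_that("filter_prevalence drops rare diseases only", {
  n <- 117392
  df <- data.frame(rare = c(rep(1L, 117), rep(0L, n - 117)),
                   kept = c(rep(1L, 118), rep(0L, n - 118)),
                   zero = rep(0L, n))
  co <- make_cohort(df)
  expect_message(f <- filter_prevalence(co), "dropping 2")
  expect_setequal(cohort_diseases(f), "kept") # 118 = ceil(0.001 * 117392)
  expect_true(all(c("sex", "age") %in% names(f$data)))
  expect_identical(filter_prevalence(co, min_prevalence = 0)$data, co$data)
})

test_that("bin_age and code_obesity follow the stated conventions", {
  expect_equal(bin_age(c(55, 63, 70)), c(0L, 1L, 2L))
  expect_equal(bin_age(60), 1L) # left-closed boundary
  expect_equal(bin_age(c(59.999, 67.999, 68)), c(0L, 1L, 2L))
  eq <- bin_age(1:99, mode = "equal_frequency")
  expect_equal(unname(table(eq)), array(c(33L, 33L, 33L)),
               ignore_attr = TRUE)
  expect_equal(code_obesity(c(30, 29.9, 45)), c(1L, 0L, 1L))
  expect_message(ob <- code_obesity(c(25, NA)), "1 subject")
  expect_identical(ob, c(0L, NA_integer_))
})

test_that("whole module is reproducible bit for bit", {
  gen <- function() {
    spec <- simulation_spec(n_nodes = 8, n_subjects = 500,
                            edge_density = 0.2, max_parents = 3, seed = 77)
    bn <- sample_cpts(sample_random_dag(spec), spec)
    simulate_onsets(simulate_cohort(bn), bn)
  }
  expect_identical(gen(), gen())
})

test_that("truth labels partition disease pairs", {
  bn <- chain_bn(4, prevalence = 0.1)
  tl <- truth_labels(bn)
  expect_equal(nrow(tl), 6L)
  expect_equal(sum(tl$label == "direct"), 3L)
  expect_equal(sum(tl$label == "connected"), 3L) # chain: all d-connected
})
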