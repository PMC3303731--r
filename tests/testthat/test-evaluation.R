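test_that("MCC anchors and degenerate convention", {
  expect_equal(mcc(contingency_table(10, 10, 0, 0)), 1)
  expect_equal(mcc(contingency_table(0, 0, 10, 10)), -1)
  expect_equal(mcc(contingency_table(5, 5, 5, 5)), 0)
  expect_equal(mcc(contingency_table(0, 7, 0, 3)), 0)  # empty margin -> 0
  expect_error(contingency_table(0, 0, 0, 0), "empty")
  expect_error(contingency_table(-1, 1, 1, 1), "nonnegative")
})

test_that("MCC equals the Pearson correlation of binary vectors", {
  expect_equal(mcc(contingency_table(8, 1, 3, 2)), mcc_pearson(8, 1, 3, 2))
  set.seed(51)
  for (i in 1:1000) {
    ct <- rpois(4, lambda = 5)
    if (sum(ct) == 0) next
    expect_equal(mcc(contingency_table(ct[1], ct[2], ct[3], ct[4])),
                 mcc_pearson(ct[1], ct[2], ct[3], ct[4]),
                 tolerance = 1e-12)
  }
})

test_that("eval_metrics identities hold", {
  t <- contingency_table(8, 1, 3, 2)
  m <- eval_metrics(t)
  expect_equal(m$accuracy * 14, 8 + 1)
  expect_equal(m$sensitivity, 8 / 10)
  expect_equal(m$specificity, 1 / 4)
  expect_true(m$mcc >= -1 && m$mcc <= 1)
  # MCC invariant under tp<->tn, fp<->fn swap
  expect_equal(mcc(contingency_table(1, 8, 2, 3)), m$mcc)
  # undefined sensitivity flag
  expect_true(is.na(eval_metrics(contingency_table(0, 5, 2, 0))$sensitivity))
})

test_that("predict_label applies the two-sided perturbation rule", {
  expect_identical(predict_label(c(4.6, -2.5, 1.9, -1.9), tau = 2),
                   c("disease", "disease", "neutral", "neutral"))
  expect_identical(predict_label(-2.5, tau = 2, rule = "destabilizing"),
                   "neutral")
  expect_identical(predict_label(2.0, tau = 2), "neutral")
})

test_that("strategy metrics equal exhaustive enumeration on toy data", {
  vals <- rbind(c(2.6, 0.4), c(1.5, -3.0), c(0.2, 0.1))
  m1 <- toy_ddg_matrix(vals, protein_id = "P1")
  m2 <- toy_ddg_matrix(rbind(c(4.0, 4.5), c(-0.5, 0.5)),
                       protein_id = "P2")
  m <- ddg_matrix(rbind(m1$sas, m2$sas), rbind(m1$cells, m2$cells),
                  rbind(m1$conformers, m2$conformers))
  labs <- c("disease", "disease", "neutral", "disease", "neutral")
  labels <- toy_labels(m, labs)
  rows <- ddg_rows(m)
  for (s in c("global", "min", "max", "mean")) {
    got <- evaluate_strategy(m, labels, s, tau = 2)
    want <- enum_strategy_metrics(rows, labs, 2, s)
    expect_equal(got$metrics$mcc, want$mcc, info = s)
    expect_equal(got$metrics$accuracy, want$accuracy, info = s)
    expect_equal(got$metrics$specificity, want$specificity, info = s)
    expect_equal(got$metrics$sensitivity, want$sensitivity, info = s)
  }
  # also under a missing cell
  vals_na <- vals
  vals_na[1, 2] <- NA
  mna <- toy_ddg_matrix(vals_na, protein_id = "P1")
  labna <- toy_labels(mna, labs[1:3])
  rowsna <- ddg_rows(mna)
  for (s in c("global", "max")) {
    got <- evaluate_strategy(mna, labna, s, tau = 2)
    want <- enum_strategy_metrics(rowsna, labs[1:3], 2, s)
    expect_equal(got$metrics$mcc, want$mcc, info = s)
  }
})

test_that("separable data yields MCC 1 for every strategy", {
  set.seed(52)
  vals <- rbind(matrix(runif(8, 2.5, 6), 4),      # disease, all above tau
                matrix(runif(6, -1.5, 1.5), 3))   # neutral, all inside
  m <- toy_ddg_matrix(vals)
  labels <- toy_labels(m, c(rep("disease", 4), rep("neutral", 3)))
  for (s in c("global", "min", "max", "mean", "random")) {
    r <- evaluate_strategy(m, labels, s, tau = 2, seed = 5,
                           n_resamples = 50)
    expect_equal(r$metrics$mcc, 1, info = s)
    expect_equal(r$metrics$accuracy, 1, info = s)
  }
})

test_that("single-conformer ensembles make all strategies identical", {
  set.seed(53)
  vals <- matrix(rnorm(8, 1.5, 2), 8, 1)
  m <- toy_ddg_matrix(vals)
  labels <- toy_labels(m, sample(c("disease", "neutral"), 8,
                                 replace = TRUE, prob = c(.6, .4)))
  base <- evaluate_strategy(m, labels, "global", tau = 2)$metrics
  for (s in c("min", "max", "mean", "random")) {
    r <- evaluate_strategy(m, labels, s, tau = 2, seed = 9,
                           n_resamples = 200)$metrics
    expect_equal(r$mcc, base$mcc, tolerance = 1e-12, info = s)
    expect_equal(r$accuracy, base$accuracy, tolerance = 1e-12, info = s)
    expect_equal(r$specificity, base$specificity, tolerance = 1e-12,
                 info = s)
    expect_equal(r$sensitivity, base$sensitivity, tolerance = 1e-12,
                 info = s)
  }
})

test_that("min/max strategy ordering holds on nonnegative ddG data", {
  set.seed(54)
  vals <- matrix(abs(rnorm(60, 2, 1.5)), 20, 3)
  m <- toy_ddg_matrix(vals)
  labels <- toy_labels(m, sample(c("disease", "neutral"), 20,
                                 replace = TRUE))
  lo <- evaluate_strategy(m, labels, "min", tau = 2)$metrics
  hi <- evaluate_strategy(m, labels, "max", tau = 2)$metrics
  expect_gte(lo$specificity, hi$specificity)
  expect_lte(lo$sensitivity, hi$sensitivity)
})

test_that("the random strategy is seeded and converges over resamples", {
  set.seed(55)
  ds <- generate_dataset(generator_config(n_proteins = 30, seed = 55))
  a <- evaluate_strategy(ds$ddg, ds$sas, "random", seed = 7,
                         n_resamples = 400)
  b <- evaluate_strategy(ds$ddg, ds$sas, "random", seed = 7,
                         n_resamples = 400)
  expect_identical(a$metrics$mcc, b$metrics$mcc)
  expect_length(a$resample_mcc, 400L)
  # independent seeds agree within a few standard errors of the mean
  c2 <- evaluate_strategy(ds$ddg, ds$sas, "random", seed = 8,
                          n_resamples = 400)
  se <- sd(a$resample_mcc) / sqrt(400)
  expect_lt(abs(a$metrics$mcc - c2$metrics$mcc), 6 * se)
})

test_that("random significance follows the add-one formula", {
  # separable data: reference (max) beats every resample
  vals <- rbind(matrix(5, 4, 2), matrix(0.5, 3, 2))
  vals[1, 1] <- 1.0  # make resamples imperfect sometimes
  m <- toy_ddg_matrix(vals)
  labels <- toy_labels(m, c(rep("disease", 4), rep("neutral", 3)))
  sig <- random_significance(m, labels, tau = 2, reference = "max",
                             seed = 3, n_resamples = 999)
  k <- sum(sig$resample_mcc >= sig$reference_mcc)
  expect_equal(sig$p_value, (k + 1) / 1000)
  expect_gt(sig$p_value, 0)
  expect_lte(sig$p_value, 1)

  # single-conformer dataset: every resample equals the reference -> p = 1
  m1 <- toy_ddg_matrix(matrix(c(5, 5, 0.5, 3), 4, 1))
  lab1 <- toy_labels(m1, c("disease", "disease", "neutral", "neutral"))
  sig1 <- random_significance(m1, lab1, tau = 2, reference = "max",
                              seed = 1, n_resamples = 99)
  expect_equal(sig1$p_value, 1)

  # random as its own reference: p near 0.5 on symmetric data
  set.seed(56)
  ds <- generate_dataset(generator_config(n_proteins = 60, seed = 56))
  sigr <- random_significance(ds$ddg, ds$sas, reference = "random",
                              seed = 11, n_resamples = 500)
  expect_gt(sigr$p_value, 0.25)
  expect_lt(sigr$p_value, 0.75)
})

test_that("per-conformer metrics match hand enumeration", {
  vals <- rbind(c(3.0, 0.5),   # disease: c1 right, c2 wrong
                c(4.0, 4.2),   # disease: both right
                c(0.5, 0.6),   # neutral: both right
                c(2.5, 1.0))   # neutral: c1 wrong, c2 right
  m <- toy_ddg_matrix(vals)
  labs <- c("disease", "disease", "neutral", "neutral")
  labels <- toy_labels(m, labs)
  pc <- per_conformer_metrics(m, labels, "P1", tau = 2)
  expect_identical(nrow(pc), 2L)
  want1 <- enum_metrics_from_counts(enum_counts(
    c(TRUE, TRUE, FALSE, FALSE), abs(vals[, 1]) > 2))
  want2 <- enum_metrics_from_counts(enum_counts(
    c(TRUE, TRUE, FALSE, FALSE), abs(vals[, 2]) > 2))
  expect_equal(pc$mcc, c(want1$mcc, want2$mcc))
  expect_equal(attr(pc, "mcc_range"), range(c(want1$mcc, want2$mcc)))
  # identical columns give identical metrics, range width 0
  m2 <- toy_ddg_matrix(cbind(vals[, 1], vals[, 1]))
  pc2 <- per_conformer_metrics(m2, toy_labels(m2, labs), "P1", tau = 2)
  expect_equal(diff(attr(pc2, "mcc_range")), 0)
  expect_equal(pc2$mcc[1], pc2$mcc[2])
  # a perfectly agreeing conformer scores MCC 1
  m3 <- toy_ddg_matrix(cbind(vals[, 1], c(3.0, 4.0, 0.5, 1.0)))
  pc3 <- per_conformer_metrics(m3, toy_labels(m3, labs), "P1", tau = 2)
  expect_equal(max(pc3$mcc), 1)
})

test_that("perfect-conformer fraction equals a brute-force row scan", {
  set.seed(57)
  vals <- matrix(rnorm(40, 1.5, 2), 10, 4)
  vals[2, 3] <- NA
  m <- toy_ddg_matrix(vals)
  labs <- sample(c("disease", "neutral"), 10, replace = TRUE)
  labels <- toy_labels(m, labs)
  got <- perfect_conformer_fraction(m, labels, tau = 2)
  want <- mean(vapply(1:10, function(i) {
    v <- vals[i, !is.na(vals[i, ])]
    any((abs(v) > 2) == (labs[i] == "disease"))
  }, logical(1)))
  expect_equal(got, want)
  # single-conformer identity: fraction equals global per-SAS accuracy
  m1 <- toy_ddg_matrix(vals[, 1, drop = FALSE])
  g <- evaluate_strategy(m1, toy_labels(m1, labs), "global", tau = 2)
  expect_equal(perfect_conformer_fraction(m1, toy_labels(m1, labs),
                                          tau = 2),
               g$metrics$accuracy)
})

test_that("bound-state enrichment identifies the max-ddG conformer", {
  vals1 <- rbind(c(1.0, 6.0, 2.0), c(0.5, 1.5, 1.0))  # max in c2
  m1 <- toy_ddg_matrix(vals1, protein_id = "P1")
  m2 <- toy_ddg_matrix(rbind(c(3.0, 1.0)), protein_id = "P2")  # max in c1
  m <- ddg_matrix(rbind(m1$sas, m2$sas), rbind(m1$cells, m2$cells),
                  rbind(m1$conformers, m2$conformers))
  flags <- data.frame(
    protein_id = c(rep("P1", 3), rep("P2", 2)),
    conformer_id = c(sprintf("P1_c%02d", 1:3), sprintf("P2_c%02d", 1:2)),
    bound = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  enr <- bound_state_enrichment(m, flags)
  expect_equal(enr$fraction_bound, 0.5)  # P1 bound, P2 unbound max
  expect_identical(enr$n_proteins, 2L)
  # all bound -> 1
  flags$bound <- TRUE
  expect_equal(bound_state_enrichment(m, flags)$fraction_bound, 1)
  # tie: any tied bound conformer counts
  mt <- toy_ddg_matrix(rbind(c(2.0, 2.0)), protein_id = "P3")
  ft <- data.frame(protein_id = "P3",
                   conformer_id = sprintf("P3_c%02d", 1:2),
                   bound = c(FALSE, TRUE))
  expect_equal(bound_state_enrichment(mt, ft)$fraction_bound, 1)
  expect_error(bound_state_enrichment(mt, ft[0, ]), "bound/unbound")
})

test_that("KS statistic matches the ECDF-scan oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(1:4, 11:14)$statistic, 1)
  d <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5))
  expect_equal(d$statistic, ks_D_oracle(c(1, 2, 3), c(1.5, 2.5)))
  set.seed(58)
  for (i in 1:50) {
    x <- rnorm(sample(2:30, 1))
    y <- rnorm(sample(2:30, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(x, y)
    expect_equal(got$statistic, ks_D_oracle(x, y))
    # asymptotic p agrees with the reference implementation; the reference
    # evaluates the Kolmogorov distribution through the dual theta series,
    # so agreement is to ~1e-4, not machine precision
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 5e-4)
  }
  expect_error(ks_two_sample(1, 1:3), "at least 2")
})

test_that("disease/neutral ddG distributions separate in synthetic data", {
  ds <- generate_dataset(generator_config(seed = 59))
  su <- summarize_sas_table(ds$ddg, labels = ds$sas)
  ks_min <- ks_two_sample(su$ddg_min[su$label == "disease"],
                          su$ddg_min[su$label == "neutral"])
  ks_max <- ks_two_sample(su$ddg_max[su$label == "disease"],
                          su$ddg_max[su$label == "neutral"])
  expect_lt(ks_min$p_value, 1e-5)
  expect_lt(ks_max$p_value, 1e-5)
})
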