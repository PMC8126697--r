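test_that("auprc matches exhaustive threshold enumeration", {
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)),
               auprc_oracle(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)))
  # reversed scores on a perfect ranking hit the oracle's minimum
  expect_equal(auprc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)),
               auprc_oracle(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)))
  set.seed(10)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))       # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auprc(labels, scores), auprc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(auprc(c(1, 1), c(0.4, 0.5)), "positive and one negative")
  expect_error(auprc(c(0.5, 1), c(0.4, 0.5)), "0/1")
})

test_that("onset metrics: MAE arithmetic and strict 5-s tolerance", {
  expect_equal(onset_mae(c(10, 20), c(12, 16)), 3)
  expect_equal(onset_mae(1:5, 1:5), 0)
  expect_error(onset_mae(numeric(0), numeric(0)), "no ictal")
  set.seed(11)
  for (i in 1:50) {
    t0 <- runif(8, 0, 90); t1 <- t0 + rnorm(8, 0, 10)
    expect_lte(onset_mae(t0, t1), max(abs(t1 - t0)))
  }
  expect_equal(tolerance_accuracy(rep(0, 3), c(4.9, 5.0, 5.1)), 1 / 3)
  expect_equal(tolerance_accuracy(c(1, 2), c(1, 2)), 1)
  expect_equal(tolerance_accuracy(c(1, 2), c(1, 2.5), tol = 0), 0.5)
})

test_that("select_seed honors scenario semantics and pairing rules", {
  ann <- data.frame(
    epoch_id = paste0("e", 1:6),
    patient_id = "P01",
    recorded_at = c("2021-01-05", "2021-01-02", "2021-01-09",
                    "2021-01-01", "2021-01-03", "2021-01-04"),
    trigger = c("detection", "detection", "detection",
                "scheduled", "scheduled", "detection"),
    s = c(1, 1, 1, 0, 0, 0), t_seconds = c(10, 20, 30, NA, NA, NA))
  ss <- select_seed(ann, 2, "earliest_consecutive", seed = 1)
  expect_identical(ss$ictal_ids, c("e2", "e1"))   # chronologically first
  expect_true(all(ss$interictal_ids %in% c("e4", "e5")))  # scheduled s=0 only
  empty <- select_seed(ann, 0, "random", seed = 1)
  expect_length(empty$ictal_ids, 0)
  a <- select_seed(ann, 2, "random", seed = 5)
  b <- select_seed(ann, 2, "random", seed = 5)
  expect_identical(a, b)
  expect_error(select_seed(ann, 4, "random"), "4 requested")
  expect_error(select_seed(ann, 3, "random"), "scheduled non-ictal")
})

test_that("inclusion filter applies the strict > max_seed + 5 rule", {
  tab <- load_cohort_table()
  expect_length(inclusion_filter(tab, max_seed = 30), 12)
  rec <- data.frame(patient = c("a", "b"), n_ictal_patterns = c(35, 36))
  expect_identical(inclusion_filter(rec, 30), "b")
  expect_identical(inclusion_filter(rec, 0), c("a", "b"))
})

test_that("kruskal-wallis H matches hand computation and stats oracle", {
  expect_equal(kruskal_wallis_by_site(rep(1, 6),
                                      rep(c("a", "b"), 3))$H, 0)
  kw <- kruskal_wallis_by_site(c(1, 2, 3, 4, 5, 6),
                               rep(c("a", "b"), each = 3))
  # ranks 1..6; rank sums 6 and 15: H = 12/42 * (12 + 75) - 21
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  set.seed(12)
  for (i in 1:20) {
    v <- round(runif(12), 2)                    # with ties
    g <- sample(c("a", "b", "c"), 12, replace = TRUE)
    if (length(unique(g)) < 2) next
    ref <- stats::kruskal.test(v, factor(g))
    kw <- kruskal_wallis_by_site(v, g)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-squared p is consistent with a permutation oracle", {
  set.seed(13)
  v <- c(0.889, 0.83, 0.974, 0.863, 0.93, 0.879,
         0.836, 0.767, 0.724, 0.827, 0.673, 0.782,
         0.705, 0.67, 0.769, 0.786, 0.898, 0.807)
  g <- rep(c("hippocampus", "neocortex", "developmental"), each = 6)
  kw <- kruskal_wallis_by_site(v, g)
  perm <- replicate(1000, kruskal_wallis_by_site(v, sample(g))$H)
  p_perm <- mean(perm >= kw$H - 1e-12)
  se <- sqrt(max(p_perm * (1 - p_perm), 1e-4) / 1000)
  expect_lt(abs(kw$p_value - p_perm), 4 * se + 0.02)
})

test_that("lopo_evaluate keeps seed and test sets disjoint per cell", {
  co <- small_cohort()
  spec <- tiny_spec(3, dropout_rate = 0)
  cfg <- train_config(n_epochs = 1, batch_size = 8,
                      final_const_epochs = 0, seed = 1)
  ev <- lopo_evaluate(co, scenario = "random", seed_sizes = c(0L, 2L),
                      net_spec = spec, train_cfg = cfg,
                      augment_cfg = augment_config(enabled = FALSE),
                      seed = 3, n_boot = 100)
  # every patient has 8 ictal epochs > 2 + 5, so all qualify
  expect_equal(nrow(ev$results), 3 * 2)
  expect_setequal(ev$results$seed_size, c(0, 2))
  # n = 0: the whole patient history is test; n = 2: minus 4 seed epochs
  expect_true(all(ev$results$n_test[ev$results$seed_size == 0] == 16))
  expect_true(all(ev$results$n_test[ev$results$seed_size == 2] == 12))
  expect_true(all(ev$results$auprc >= 0 & ev$results$auprc <= 1))
  expect_true(all(ev$results$onset_mae >= 0))
  expect_named(ev$summary, c("0", "2"))
  # scenario 2 never reaches past the seed epochs chronologically
  p1 <- co$annotations[co$annotations$patient_id == "P01", ]
  ss <- select_seed(p1, 3, "earliest_consecutive", seed = 1)
  ict <- p1[p1$s == 1, ]
  picked <- ict$recorded_at[match(ss$ictal_ids, ict$epoch_id)]
  expect_true(all(picked <= min(setdiff(ict$recorded_at, picked))))
})
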