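#' Area under the precision-recall curve
#'
#' Step-curve (average-precision) integration by a descending-score
#' threshold sweep; tied scores are handled as a single threshold. No
#' interpolation, which avoids optimism under class imbalance. Matches an
#' exhaustive all-thresholds enumeration.
#'
#' @param labels binary vector (needs at least one positive and one
#'   negative).
#' @param scores numeric vector, higher = more ictal.
#' @return area in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) stop_fmt("labels must be 0/1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    stop_fmt("need at least one positive and one negative label")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # indices ending each tie group (one threshold per unique score)
  last <- which(diff(sc) != 0)
  last <- c(last, length(sc))
  tp <- cumsum(lab)[last]
  pred_pos <- last
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Mean absolute onset error (seconds)
#'
#' @param t true onsets for ictal epochs.
#' @param t_hat predicted onsets.
#' @return `mean(|t_hat - t|)`.
#' @export
onset_mae <- function(t, t_hat) {
  if (length(t) == 0L) stop_fmt("no ictal epochs supplied")
  stopifnot(length(t) == length(t_hat), all(is.finite(t)))
  mean(abs(t_hat - t))
}

#' Fraction of onsets within a tolerance window
#'
#' Strict inequality: `|t_hat - t| < tol`, default +/- 5 s (half a
#' typical 20-s clinical review page to each side).
#'
#' @inheritParams onset_mae
#' @param tol tolerance in seconds; the degenerate `tol = 0` counts exact
#'   hits.
#' @return fraction in `[0, 1]`.
#' @export
tolerance_accuracy <- function(t, t_hat, tol = 5) {
  if (length(t) == 0L) stop_fmt("no ictal epochs supplied")
  stopifnot(length(t) == length(t_hat))
  if (tol == 0) mean(t_hat == t) else mean(abs(t_hat - t) < tol)
}

#' Select a seed set for one held-out patient
#'
#' Scenario `"random"` draws `n` ictal epochs uniformly without
#' replacement from the patient's history; scenario
#' `"earliest_consecutive"` takes the `n` chronologically first ictal
#' epochs (the new-implant setting, using no information recorded after
#' them). Either way the seed is paired with `n` interictal epochs drawn
#' uniformly from the patient's scheduled, non-ictal recordings.
#'
#' @param annotations the cohort annotation rows of one patient.
#' @param n seed size (0 gives an empty seed set).
#' @param scenario `"random"` or `"earliest_consecutive"`.
#' @param seed integer seed for the draws.
#' @return list of class `seed_set`: `ictal_ids`, `interictal_ids`,
#'   `scenario`, `patient_id`.
#' @export
select_seed <- function(annotations, n,
                        scenario = c("random", "earliest_consecutive"),
                        seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(length(unique(annotations$patient_id)) <= 1L, n >= 0)
  ict <- annotations[annotations$s == 1, ]
  pool <- annotations[annotations$s == 0 &
                        annotations$trigger == "scheduled", ]
  if (nrow(ict) < n)
    stop_fmt("infeasible seed: %d ictal epochs available, %d requested",
             nrow(ict), n)
  if (nrow(pool) < n)
    stop_fmt(paste0("infeasible seed: %d scheduled non-ictal epochs ",
                    "available, %d requested"), nrow(pool), n)
  with_seed(seed, {
    ictal_ids <- if (n == 0L) character(0)
    else if (scenario == "random") sample(ict$epoch_id, n)
    else ict$epoch_id[order(ict$recorded_at)][seq_len(n)]
    inter_ids <- if (n == 0L) character(0) else sample(pool$epoch_id, n)
    structure(list(ictal_ids = ictal_ids, interictal_ids = inter_ids,
                   scenario = scenario,
                   patient_id = annotations$patient_id[1] %||% NA_character_),
              class = "seed_set")
  })
}

bootstrap_ci <- function(x, n_boot = 2000L, seed = 1L, level = 0.95) {
  if (length(x) < 2L) return(c(NA_real_, NA_real_))
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(x, length(x), replace = TRUE)), numeric(1))
    unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Leave-one-patient-out evaluation over seed sizes
#'
#' For every qualifying held-out patient and every seed size `n`: a fresh
#' network (one-hot sized to the whole cohort) is trained on all other
#' patients' epochs plus the patient's seed set (`n` ictal + `n` paired
#' scheduled interictal epochs), then evaluated on the patient's
#' remaining epochs — never on seed epochs. At `n = 0` the held-out
#' patient's one-hot index exists but is untrained, which is what makes
#' cross-patient transference measurable from zero seeds upward.
#'
#' @param cohort an `ieeg_cohort`.
#' @param scenario `"random"` (scenario 1) or `"earliest_consecutive"`
#'   (scenario 2).
#' @param seed_sizes integer vector (default `seq(0, 30, by = 5)`).
#' @param net_spec an [network_spec()] sized to the cohort; built fresh
#'   per cell.
#' @param train_cfg a [train_config()].
#' @param augment_cfg an [augment_config()].
#' @param seed master seed for seed-set draws, initialization and
#'   training.
#' @param n_boot bootstrap resamples for the across-patient 95% CI.
#' @param verbose print progress.
#' @return list with `results` (one row per patient x seed size:
#'   `patient, site, scenario, seed_size, auprc, onset_mae,
#'   tolerance_fraction, n_test`), `summary` (per seed size: mean, SD,
#'   bootstrap CI), and `failed` (infeasible cells with diagnostics).
#' @export
lopo_evaluate <- function(cohort, scenario = "random",
                          seed_sizes = seq(0L, 30L, by = 5L),
                          net_spec = NULL,
                          train_cfg = train_config(),
                          augment_cfg = augment_config(),
                          seed = 1L, n_boot = 2000L, verbose = FALSE) {
  stopifnot(inherits(cohort, "ieeg_cohort"))
  patients <- unique(cohort$annotations$patient_id)
  if (length(patients) < 2L) stop_fmt("need at least 2 patients")
  net_spec <- net_spec %||% network_spec(n_patients = length(patients))
  stopifnot(net_spec$n_patients == length(patients))
  qual <- inclusion_filter(cohort$metadata, max_seed = max(seed_sizes))
  rows <- list()
  failed <- list()
  for (p in qual) {
    p_ann <- cohort$annotations[cohort$annotations$patient_id == p, ]
    other_ids <- cohort$annotations$epoch_id[
      cohort$annotations$patient_id != p]
    for (n in seed_sizes) {
      cell_seed <- derive_seed(seed, sprintf("lopo:%s:%s:%d", scenario, p, n))
      ss <- tryCatch(
        select_seed(p_ann, n, scenario, seed = cell_seed),
        error = function(e) e)
      if (inherits(ss, "error")) {
        failed[[length(failed) + 1L]] <- data.frame(
          patient = p, seed_size = n, reason = conditionMessage(ss))
        next
      }
      seed_ids <- c(ss$ictal_ids, ss$interictal_ids)
      train_ids <- c(other_ids, seed_ids)
      test_ann <- p_ann[!p_ann$epoch_id %in% seed_ids, ]
      if (verbose)
        message(sprintf("holdout %s, seed %d: train %d, test %d",
                        p, n, length(train_ids), nrow(test_ann)))
      net <- build_network(net_spec, seed = cell_seed)
      cfg <- train_cfg
      cfg$seed <- cell_seed
      examples <- cohort_examples(cohort, patient_levels = patients,
                                  epoch_ids = train_ids)
      net <- train_network(net, examples, cfg, augment_cfg)
      test_ex <- cohort_examples(cohort, patient_levels = patients,
                                 epoch_ids = test_ann$epoch_id)
      preds <- predict_examples(net, test_ex)
      test_ann <- test_ann[match(vapply(test_ex, `[[`, "", "epoch_id"),
                                 test_ann$epoch_id), ]
      ict <- test_ann$s == 1
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p,
        site = cohort$metadata$implantation_site[
          match(p, cohort$metadata$patient)],
        scenario = scenario, seed_size = n,
        auprc = auprc(test_ann$s, preds$s_hat),
        onset_mae = onset_mae(test_ann$t_seconds[ict], preds$t_hat[ict]),
        tolerance_fraction = tolerance_accuracy(test_ann$t_seconds[ict],
                                                preds$t_hat[ict]),
        n_test = nrow(test_ann), stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  summary <- lapply(split(results, results$seed_size), function(df) {
    list(seed_size = df$seed_size[1], n_patients = nrow(df),
         auprc_mean = mean(df$auprc), auprc_sd = sd(df$auprc),
         auprc_ci95 = bootstrap_ci(df$auprc, n_boot,
                                   derive_seed(seed, "boot_auprc")),
         mae_mean = mean(df$onset_mae), mae_sd = sd(df$onset_mae),
         mae_ci95 = bootstrap_ci(df$onset_mae, n_boot,
                                 derive_seed(seed, "boot_mae")),
         tolerance_mean = mean(df$tolerance_fraction))
  })
  list(results = results, summary = summary,
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}

predict_examples <- function(net, examples, batch = 32L) {
  out_s <- numeric(length(examples))
  out_t <- numeric(length(examples))
  for (start in seq(1L, length(examples), by = batch)) {
    take <- start:min(start + batch - 1L, length(examples))
    X <- array(0, c(IEEG_CHANNELS, IEEG_SAMPLES, length(take)))
    for (i in seq_along(take)) X[, , i] <- examples[[take[i]]]$samples
    pidx <- vapply(examples[take], `[[`, numeric(1), "patient_index")
    pr <- net_predict(net, X, pidx)
    out_s[take] <- pr$s_hat
    out_t[take] <- pr$t_hat
  }
  data.frame(s_hat = out_s, t_hat = out_t)
}

#' Kruskal-Wallis rank test across implant-site groups
#'
#' Tie-corrected H statistic with a chi-squared approximation on
#' `k - 1` degrees of freedom; the conventional significance threshold
#' is 0.05.
#'
#' @param values numeric outcomes (e.g. per-patient AUPRC).
#' @param groups group labels (e.g. implant sites), >= 2 distinct.
#' @return list `H`, `df`, `p_value`.
#' @export
kruskal_wallis_by_site <- function(values, groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  groups <- as.factor(droplevels(as.factor(groups)))
  k <- nlevels(groups)
  if (k < 2L) stop_fmt("need at least 2 groups")
  n <- length(values)
  r <- rank(values)
  ssum <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(ssum^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) H <- H / tie_corr
  list(H = H, df = k - 1L, p_value = pchisq(H, k - 1L, lower.tail = FALSE))
}
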