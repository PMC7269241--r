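#' Regional error summary across maps
#'
#' Per-map spatial mean error (percent deviation from unity) over the brain
#' mask, the AD-related mask and the non-AD brain (brain minus AD), plus the
#' across-map mean and SD for each region — the headline MRAC error
#' statistics of the study.
#'
#' @param error_maps list of `error_map`s (or `volume_grid` fields).
#' @param template a `template_space`.
#' @return list with `per_map` (data.frame: map_id, institution, brain_pct,
#'   ad_pct, nonad_pct) and `summary` (data.frame: region, mean_pct, sd_pct).
#' @export
regional_error_summary <- function(error_maps, template) {
  if (!length(error_maps)) stop("regional_error_summary: no error maps")
  if (sum(template$ad_mask$data) == 0 ||
      sum(template$brain_mask$data > 0 & template$ad_mask$data == 0) == 0)
    stop("regional_error_summary: empty region in template")
  rows <- lapply(seq_along(error_maps), function(i) {
    em <- error_maps[[i]]
    fld <- if (inherits(em, "error_map")) em$field else em
    st <- error_map_stats(fld, template)
    data.frame(map_id = if (inherits(em, "error_map")) em$map_id
                        else sprintf("map%02d", i),
               institution = if (inherits(em, "error_map")) em$institution
                             else NA_character_,
               brain_pct = st[["brain_pct"]], ad_pct = st[["ad_pct"]],
               nonad_pct = st[["nonad_pct"]], stringsAsFactors = FALSE)
  })
  per_map <- do.call(rbind, rows)
  summary <- data.frame(
    region = c("brain", "ad", "nonad"),
    mean_pct = c(mean(per_map$brain_pct), mean(per_map$ad_pct),
                 mean(per_map$nonad_pct)),
    sd_pct = c(stats::sd(per_map$brain_pct), stats::sd(per_map$ad_pct),
               stats::sd(per_map$nonad_pct)),
    stringsAsFactors = FALSE)
  list(per_map = per_map, summary = summary)
}

#' Simulated-minus-baseline PET score differences
#'
#' @param score_table data.frame from [run_cross_simulation()] (baseline
#'   rows have `error_map_id == "none"`).
#' @return list with `per_row` (the simulated rows plus `score_diff`),
#'   `overall` (mean, sd, n) and `per_map` (data.frame map_id, mean_diff,
#'   sd_diff, n).
#' @export
score_differences <- function(score_table) {
  base <- score_table[score_table$error_map_id == "none", ]
  sim <- score_table[score_table$error_map_id != "none", ]
  missing <- setdiff(sim$subject_id, base$subject_id)
  if (length(missing))
    stop("score_differences: no baseline for subject(s) ",
         paste(utils::head(missing, 3), collapse = ", "))
  baseline_score <- stats::setNames(base$pet_score, base$subject_id)
  sim$score_diff <- sim$pet_score - baseline_score[sim$subject_id]
  # flagged pairs (AD t-sum at/below the PET-score domain bound) carry NA
  # scores; they stay in per_row but are dropped from the aggregates
  ok <- !is.na(sim$score_diff)
  agg <- stats::aggregate(score_diff ~ error_map_id, data = sim[ok, ],
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  per_map <- data.frame(map_id = agg$error_map_id,
                        mean_diff = agg$score_diff[, "mean"],
                        sd_diff = agg$score_diff[, "sd"],
                        n = agg$score_diff[, "n"],
                        stringsAsFactors = FALSE)
  list(per_row = sim,
       overall = list(mean = mean(sim$score_diff[ok]),
                      sd = stats::sd(sim$score_diff[ok]), n = sum(ok),
                      n_flagged = sum(!ok)),
       per_map = per_map)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k successes, `n` trials, `level` confidence level.
#' @param n number of trials.
#' @param level confidence level.
#' @return c(low, high).
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic accuracy at a fixed PET-score cutoff
#'
#' Predicts positive when `score >= cutoff`. Task 1 (AD vs NC) labels AD as
#' positive; task 2 (MCI conversion) labels converters as positive. Metrics
#' with zero denominators are returned as `NA` and flagged in `undefined`.
#'
#' @param scores numeric PET scores.
#' @param truth logical, `TRUE` = positive class.
#' @param cutoff decision threshold.
#' @param task label (`"AD_vs_NC"` or `"MCI_conversion"`).
#' @param error_map_id identifier carried into the summary.
#' @param level confidence level for Wilson intervals.
#' @return a `diagnostic_summary`: list with counts (tp, fp, tn, fn),
#'   `accuracy`, `sensitivity`, `specificity`, per-metric `ci` (rows low,
#'   high), `undefined`, `task`, `cutoff`, `error_map_id`.
#' @export
diagnostic_metrics <- function(scores, truth, cutoff,
                               task = "AD_vs_NC", error_map_id = "original",
                               level = 0.95) {
  if (length(scores) != length(truth))
    stop("diagnostic_metrics: scores and truth lengths differ")
  truth <- as.logical(truth)
  keep <- !is.na(scores)
  n_dropped <- sum(!keep)
  scores <- scores[keep]; truth <- truth[keep]
  pred <- scores >= cutoff
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  npos <- tp + fn; nneg <- tn + fp; ntot <- npos + nneg
  metric <- function(k, n) if (n > 0) k / n else NA_real_
  acc <- metric(tp + tn, ntot)
  sens <- metric(tp, npos)
  spec <- metric(tn, nneg)
  ci <- cbind(accuracy = wilson_ci(tp + tn, ntot, level),
              sensitivity = if (npos > 0) wilson_ci(tp, npos, level)
                            else c(NA, NA),
              specificity = if (nneg > 0) wilson_ci(tn, nneg, level)
                            else c(NA, NA))
  rownames(ci) <- c("low", "high")
  structure(list(task = task, error_map_id = error_map_id, cutoff = cutoff,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 ci = ci, n_dropped = n_dropped,
                 undefined = c(sensitivity = npos == 0,
                               specificity = nneg == 0)),
            class = "diagnostic_summary")
}

#' Rank error maps by diagnostic accuracy
#'
#' Orders per-map summaries by accuracy (descending), ties broken by
#' sensitivity then map id, and computes the across-map average / worst /
#' best of each metric (per-metric extremes, the summary-table contract) as
#' well as the best-k / worst-k map ids under the ranking.
#'
#' @param summaries list of `diagnostic_summary` objects for one task.
#' @param k how many best/worst map ids to report.
#' @return list with `table` (per-map data.frame in ranked order),
#'   `across` (data.frame metric, average, worst, best), `best_ids`,
#'   `worst_ids`.
#' @export
rank_error_maps <- function(summaries, k = 3) {
  if (!length(summaries)) stop("rank_error_maps: no summaries")
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(map_id = s$error_map_id, accuracy = s$accuracy,
               sensitivity = s$sensitivity, specificity = s$specificity,
               stringsAsFactors = FALSE)))
  ord <- order(-tab$accuracy, -tab$sensitivity, tab$map_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  across <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity"),
    average = c(mean(tab$accuracy), mean(tab$sensitivity),
                mean(tab$specificity)),
    worst = c(min(tab$accuracy), min(tab$sensitivity), min(tab$specificity)),
    best = c(max(tab$accuracy), max(tab$sensitivity), max(tab$specificity)),
    stringsAsFactors = FALSE)
  k <- min(k, nrow(tab))
  list(table = tab, across = across,
       best_ids = tab$map_id[seq_len(k)],
       worst_ids = rev(tab$map_id)[seq_len(k)])
}

#' Bland-Altman agreement between baseline and simulated scores
#'
#' @param baseline_scores,simulated_scores paired numeric vectors,
#'   length >= 2.
#' @return list with `mean_difference`, `sd_difference` (n-1 denominator),
#'   `loa_low`, `loa_high` (mean ± 1.96 SD), `n_pairs` and `pairs`
#'   (data.frame mean, difference) for plotting.
#' @export
bland_altman <- function(baseline_scores, simulated_scores) {
  if (length(baseline_scores) != length(simulated_scores))
    stop("bland_altman: paired vectors of different length (",
         length(baseline_scores), " vs ", length(simulated_scores), ")")
  keep <- !is.na(baseline_scores) & !is.na(simulated_scores)
  baseline_scores <- baseline_scores[keep]
  simulated_scores <- simulated_scores[keep]
  if (length(baseline_scores) < 2)
    stop("bland_altman: need at least 2 complete pairs")
  d <- simulated_scores - baseline_scores
  m <- mean(d); s <- stats::sd(d)
  list(mean_difference = m, sd_difference = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n_pairs = length(d),
       pairs = data.frame(mean = (baseline_scores + simulated_scores) / 2,
                          difference = d))
}

#' Compare mean score differences between institutions
#'
#' Welch two-sample t-test (two-sided) on per-map mean PET-score
#' differences grouped by institution.
#'
#' @param per_map_mean_diffs numeric vector, one value per error map.
#' @param institution_labels factor/character of the same length with
#'   exactly two levels.
#' @return list with `t_statistic`, `p_value`, `group_means`, `group_sds`,
#'   `groups`.
#' @export
compare_institutions <- function(per_map_mean_diffs, institution_labels) {
  g <- factor(institution_labels)
  if (nlevels(g) != 2)
    stop("compare_institutions: need exactly two institutions, got ",
         nlevels(g))
  ns <- table(g)
  if (any(ns < 2))
    stop("compare_institutions: each group needs >= 2 maps")
  x <- per_map_mean_diffs[g == levels(g)[1]]
  y <- per_map_mean_diffs[g == levels(g)[2]]
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    # degenerate but well-defined: no difference, no evidence
    return(list(t_statistic = 0, p_value = 1,
                group_means = c(mean(x), mean(y)), group_sds = c(0, 0),
                groups = levels(g)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       group_means = c(mean(x), mean(y)),
       group_sds = c(stats::sd(x), stats::sd(y)),
       groups = levels(g))
}
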