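#!/usr/bin/env Rscript
# Step 4 — diagnostic endpoints.
#
# Reads the score table written by step 3 and evaluates both diagnostic
# tasks at their fixed cutoffs: AD versus NC at PET score 1.0 and
# MCI-to-AD conversion at 0.79. Summarizes original (no-error) accuracy
# with Wilson 95% CIs, the average/worst/best across the 47 error maps,
# and Bland-Altman agreement for the three best and three worst maps.
#
# Writes: results/bland_altman_best_worst.csv (tables from step 3 reused)

suppressPackageStartupMessages(library(mracpet))

scores <- read.csv("results/study/scores.csv", stringsAsFactors = FALSE)
subjects <- read.csv("results/study/subjects.csv", stringsAsFactors = FALSE)

report_task <- function(label, subset_ids, positive, cutoff) {
  pos <- setNames(positive, subset_ids)
  one <- function(map_id) {
    rows <- scores[scores$error_map_id == map_id &
                     scores$subject_id %in% subset_ids, ]
    diagnostic_metrics(rows$pet_score, unname(pos[rows$subject_id]), cutoff,
                       task = label,
                       error_map_id = if (map_id == "none") "original" else map_id)
  }
  orig <- one("none")
  per_map <- lapply(setdiff(unique(scores$error_map_id), "none"), one)
  rk <- rank_error_maps(per_map)
  message(sprintf("%s (cutoff %.2f):", label, cutoff))
  message(sprintf("  original: acc %.1f%% (CI %.1f-%.1f%%), sens %.1f%%, spec %.1f%%",
                  100 * orig$accuracy, 100 * orig$ci["low", "accuracy"],
                  100 * orig$ci["high", "accuracy"],
                  100 * orig$sensitivity, 100 * orig$specificity))
  a <- rk$across
  for (i in seq_len(nrow(a)))
    message(sprintf("  %-11s average %.1f%%  worst %.1f%%  best %.1f%%",
                    a$metric[i], 100 * a$average[i], 100 * a$worst[i],
                    100 * a$best[i]))
  rk
}

ad_ids <- subjects$subject_id[subjects$group %in% c("AD", "NC")]
rk1 <- report_task("AD_vs_NC", ad_ids,
                   subjects$group[match(ad_ids, subjects$subject_id)] == "AD",
                   1.0)
mci_ids <- subjects$subject_id[subjects$group == "MCI"]
rk2 <- report_task("MCI_conversion", mci_ids,
                   subjects$converted_24mo[match(mci_ids, subjects$subject_id)],
                   0.79)

base <- scores[scores$error_map_id == "none", ]
bl <- setNames(base$pet_score, base$subject_id)
ba_rows <- do.call(rbind, lapply(c(rk1$best_ids, rk1$worst_ids), function(id) {
  sim <- scores[scores$error_map_id == id, ]
  ba <- bland_altman(unname(bl[sim$subject_id]), sim$pet_score)
  data.frame(map_id = id,
             kind = if (id %in% rk1$best_ids) "best" else "worst",
             mean_difference = ba$mean_difference,
             sd_difference = ba$sd_difference,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             n_pairs = ba$n_pairs)
}))
write.csv(ba_rows, "results/bland_altman_best_worst.csv", row.names = FALSE)
message("Bland-Altman (best/worst three maps by AD-vs-NC accuracy):")
for (i in seq_len(nrow(ba_rows)))
  message(sprintf("  %-12s (%s): mean diff %+.3f, LoA [%+.3f, %+.3f]",
                  ba_rows$map_id[i], ba_rows$kind[i],
                  ba_rows$mean_difference[i], ba_rows$loa_low[i],
                  ba_rows$loa_high[i]))
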