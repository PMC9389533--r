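#!/usr/bin/env Rscript
# The original clinical evaluation of this video CADx approach printed the
# inputs of several of its statistics (confusion counts, stratum margins,
# 2x2 error tables). Those are recomputed here exactly from the printed
# inputs — a check of the statistical machinery that needs no video data.

source("analysis/00_common.R")

# 117-video test set at the 1-s cutoff: 48/53 cancers and 50/64
# non-cancerous videos called correctly
m <- diagnostic_metrics(counts_2x2(tp = 48, fp = 14, fn = 5, tn = 50))
print(m)

# accuracy of the hardest benign stratum from its error-table margins
aim <- suppressWarnings(
  stratified_accuracy(rep("atrophy_IM", 16), rep(c(TRUE, FALSE), c(10, 6))))
cat(sprintf("atrophy+IM accuracy: %.2f (%.2f-%.2f)\n",
            round_report(aim$accuracy, 2), aim$lower, aim$upper))

# univariate error analysis, Pearson chi-square without continuity correction
sev <- matrix(c(5, 6, 5, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("moderate_severe", "mild"), c("correct", "wrong")))
sex <- matrix(c(8, 5, 2, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("male", "female"), c("correct", "wrong")))
p_sev <- pearson_chi2_2x2(sev)$p_value
p_sex <- pearson_chi2_2x2(sex)$p_value
cat(sprintf("severity vs error: p = %.3f; sex vs error: p = %.3f\n",
            round_report(p_sev, 3), round_report(p_sex, 3)))

# Wilson interval behind the printed 0.88 (0.69-0.96) for 21 correct of 24
ci <- wilson_ci(21, 24)
cat(sprintf("21/24 correct: %.2f (%.2f-%.2f)\n",
            ci$estimate, round_report(ci$lower, 2), round_report(ci$upper, 2)))

out <- list(
  headline = list(sensitivity = m$sensitivity$estimate,
                  specificity = m$specificity$estimate,
                  plr = m$plr$estimate, nlr = m$nlr$estimate,
                  accuracy = m$accuracy$estimate),
  atrophy_IM_accuracy = aim$accuracy,
  severity_chi2_p = p_sev, sex_chi2_p = p_sex,
  wilson_21_24 = list(lower = ci$lower, upper = ci$upper))
jsonlite::write_json(out, file.path(RESULTS_DIR, "reference_statistics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(RESULTS_DIR, "reference_statistics.json"), "\n")
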