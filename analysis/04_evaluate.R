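#!/usr/bin/env Rscript
# Diagnose every video at the 1-s TTROI cutoff and evaluate against the
# pathology ground truth: overall sensitivity/specificity/PLR/NLR/accuracy
# with confidence intervals, per-pathology accuracy, and — as an agreement
# demonstration — a comparison of the 1-s rule with a stricter 5-s variant
# via Cohen's kappa and the exact McNemar test.

source("analysis/00_common.R")

cohort <- get_cohort()
summaries <- summarize_videos(cohort$series, gap_s = 3)
ev <- evaluate_cohort(summaries, cohort$meta, cutoff_s = 1)
print(ev)

utils::write.table(metrics_table(ev),
                   file.path(RESULTS_DIR, "diagnostic_report.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(ev$by_pathology,
                   file.path(RESULTS_DIR, "accuracy_by_pathology.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

# a stricter reader: same streams, 5-s cutoff
strict <- classify_video(summaries$ttroi_s, cutoff_s = 5)
default <- ev$per_video$prediction[match(summaries$video_id,
                                         ev$per_video$video_id)]
truth <- ev$per_video$truth[match(summaries$video_id, ev$per_video$video_id)]
kap <- cohens_kappa(default, strict)
mcn <- mcnemar_test(default == truth, strict == truth)
cat(sprintf("\n1-s vs 5-s rule: kappa %.2f (%.2f-%.2f); McNemar b=%d c=%d p=%.3f\n",
            kap$kappa, kap$lower, kap$upper, mcn$b, mcn$c, mcn$p_value))

# univariate error analysis for the hardest benign stratum
aim <- ev$per_video[ev$per_video$pathology == "atrophy_IM", ]
if (nrow(aim) > 1 && length(unique(aim$correct)) > 1) {
  for (cov in c("severity", "range", "sex")) {
    tab <- table(aim[[cov]], aim$correct)
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      cat(sprintf("atrophy+IM errors vs %s: chi-square p = %.3f, Fisher p = %.3f\n",
                  cov, pearson_chi2_2x2(tab)$p_value, fisher_exact_2x2(tab)))
    }
  }
}
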