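#!/usr/bin/env Rscript
# ROC analysis over TTROI: AUC, the Youden-optimal cutoff, and how the
# in-sample optimum relates to the fixed 1-s operating point used for the
# headline diagnosis rule.

source("analysis/00_common.R")

cohort <- get_cohort()
summaries <- summarize_videos(cohort$series, gap_s = 3)
df <- merge(summaries, cohort$meta[, c("video_id", "truth")], by = "video_id")

roc <- roc_points(df$ttroi_s, df$truth)
utils::write.table(roc$points, file.path(RESULTS_DIR, "roc_points.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("AUC = %.3f over %d candidate thresholds\n",
            roc$auc, nrow(roc$points)))
cat(sprintf("Youden-optimal cutoff = %.3g s (J = %.3f)\n",
            best_cutoff(roc), roc$j_at_best))

at1 <- roc$points[which.min(abs(roc$points$threshold - 1)), ]
cat(sprintf("operating point at the 1-s cutoff: sens %.2f, spec %.2f\n",
            at1$sens, at1$spec))
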