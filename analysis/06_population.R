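#!/usr/bin/env Rscript
# Population structure of the timing fingerprints: night-to-night
# consistency vs between-subject heterogeneity of the history curves,
# feature comparisons between groups with multiplicity correction, and a
# global permutation test on the curve families.

suppressMessages(library(spindlepp))

manifest <- read.csv("results/cohort_manifest.csv")
curves <- read.csv("results/history_curves.csv")
features <- read.csv("results/history_features.csv")
dir.create("results/figures", showWarnings = FALSE)

lag <- sort(unique(curves$lag))
mat <- t(vapply(seq_len(nrow(manifest)), function(k) {
  sel <- curves$subject == manifest$subject[k] &
    curves$night == manifest$night[k]
  curves$modulation[sel][order(curves$lag[sel])]
}, numeric(length(lag))))

pools <- correlation_pools(mat, manifest$subject, manifest$night)
tt <- t.test(atanh(pmin(pools$intra, 1 - 1e-12)),
             atanh(pmin(pools$inter, 1 - 1e-12)))
cat(sprintf("history-curve correlations: intra-subject mean %.3f (n=%d), inter-subject mean %.3f (n=%d), t test p = %.2g\n",
            mean(pools$intra), length(pools$intra),
            mean(pools$inter), length(pools$inter), tt$p.value))

f1 <- features[features$night == 1, ]
cmp <- feature_group_tests(
  f1[, c("refractory_s", "excitatory_s", "peak_time_s", "peak_height")],
  f1$group)
write.csv(cmp, "results/feature_group_comparison.csv", row.names = FALSE)
cat("group comparisons (Welch t, Bonferroni-corrected):\n")
print(cmp[, c("feature", "mean_a", "mean_b", "t", "p_corrected", "stars")],
      digits = 3)

grpA <- mat[manifest$night == 1 & manifest$group == "reference", ]
grpB <- mat[manifest$night == 1 & manifest$group == "short_refractory", ]
perm <- global_permutation_curve_test(grpA, grpB, n_perm = 999, seed = 99)
write.csv(data.frame(lag = lag, observed_t = perm$observed_t,
                     significant = perm$mask),
          "results/curve_permutation_mask.csv", row.names = FALSE)
cat(sprintf("global permutation test on curve families: p = %.4g, %d/%d lags above the max-t threshold\n",
            perm$p_global, sum(perm$mask), length(lag)))

png("results/figures/group_mean_curves.png", 900, 600, res = 120)
plot(lag, colMeans(grpA), type = "l", lwd = 2, ylim = c(0, 2.3),
     xlab = "Lag since last spindle (s)", ylab = "Multiplicative effect",
     main = "Group mean history curves (night 1)")
lines(lag, colMeans(grpB), lwd = 2, col = "red3")
abline(h = 1, lty = 3)
rug(lag[perm$mask], col = "grey40")
legend("topright", c("reference", "short refractory"), lwd = 2,
       col = c("black", "red3"), bty = "n")
dev.off()
cat("-> results/feature_group_comparison.csv, results/curve_permutation_mask.csv\n")
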