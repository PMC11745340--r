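#!/usr/bin/env Rscript
# History modulation read-outs: per-night curves with CIs, summary features
# (refractory period, excitatory period, peak height/time), and a figure of
# a representative fitted curve against its generative truth.

suppressMessages(library(spindlepp))

manifest <- read.csv("results/cohort_manifest.csv")
dir.create("results/figures", showWarnings = FALSE)
lag_grid <- seq(0, 15, by = 0.05)

curves <- NULL
features <- NULL
for (k in seq_len(nrow(manifest))) {
  tag <- sprintf("%s_night%d", manifest$subject[k], manifest$night[k])
  fit <- model_from_json(file.path("results/models", paste0(tag, ".json")))
  cur <- history_modulation_curve(fit, lag_grid)
  f <- extract_history_features(cur)
  curves <- rbind(curves, cbind(subject = manifest$subject[k],
                                night = manifest$night[k], as.data.frame(cur)))
  features <- rbind(features, data.frame(
    subject = manifest$subject[k], group = manifest$group[k],
    night = manifest$night[k], refractory_s = f$refractory_s,
    excitatory_s = f$excitatory_s, peak_time_s = f$peak_time_s,
    peak_height = f$peak_height))
}
write.csv(curves, "results/history_curves.csv", row.names = FALSE)
write.csv(features, "results/history_features.csv", row.names = FALSE)

tag1 <- sprintf("%s_night%d", manifest$subject[1], manifest$night[1])
fit1 <- model_from_json(file.path("results/models", paste0(tag1, ".json")))
png("results/figures/history_curve_example.png", 900, 600, res = 120)
plot(history_modulation_curve(fit1, lag_grid),
     truth = true_history_curve(paper_like_scenario("paper_default"), lag_grid),
     main = sprintf("History modulation, %s (dashed: generative truth)", tag1))
dev.off()

agg <- aggregate(cbind(refractory_s, excitatory_s, peak_time_s, peak_height)
                 ~ group, features, mean)
cat("group mean history features:\n")
print(agg, digits = 3)
cat("-> results/history_curves.csv, results/history_features.csv\n")
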