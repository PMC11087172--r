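#!/usr/bin/env Rscript
# Compare ACR no-deviation passing counts across the four machines and build
# per-material HU baselines from the head/body scorecards.

library(acrct)

dir.create("results", showWarnings = FALSE)
cfg <- acr_criteria()

t4 <- score_metric_table(acr_table("table4_machines"), cfg)
write.csv(t4, "results/machine_scorecards.csv", row.names = FALSE)

counts <- reshape(t4[, c("machine", "protocol", "n_pass")],
                  idvar = "protocol", timevar = "machine",
                  direction = "wide")
names(counts) <- sub("^n_pass\\.", "", names(counts))
write.csv(counts, "results/machine_no_deviation_counts.csv",
          row.names = FALSE)
cat("No-deviation criteria met (of 9) per machine and protocol:\n")
print(counts)

# machine-to-machine comparison for the protocols all four machines ran
head_rows <- t4[t4$protocol == "Head", ]
cards <- split(head_rows, head_rows$machine)
cards <- cards[c("HyperSight", "SOMATOM Edge", "TrueBeam", "Halcyon 2.0")]
cmp <- compare_scorecards(cards, cfg)
write.csv(cmp$hu_differences, "results/head_protocol_hu_differences.csv",
          row.names = FALSE)

# clinical-style baselines from the full 11-protocol scorecards
mats <- c("acrylic", "air", "bone", "polyethylene", "water")
b_head <- build_baseline(acr_table("table2_head")[mats], cfg$baseline_tol_hu)
b_body <- build_baseline(acr_table("table2_body")[mats], cfg$baseline_tol_hu)
baselines <- data.frame(material = mats,
                        head_baseline_hu = round(b_head$baseline, 1),
                        body_baseline_hu = round(b_body$baseline, 1))
write.csv(baselines, "results/hu_baselines.csv", row.names = FALSE)
cat("\nPer-material HU baselines (mean over the 11 vendor protocols):\n")
print(baselines, row.names = FALSE)
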