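#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 199 participants, ~3 working weeks
# of monitored days each, 5-part daily behavior compositions and four daily
# outcomes, then apply the day-level validity filters. Writes the analyzed
# cohort and descriptive statistics under results/.
# Run from the repository root:  Rscript analysis/01_simulate.R

suppressMessages(library(coda24))
dir.create("results", showWarnings = FALSE)

SEED <- 20240915
sim <- simulate_emia(generator_config(seed = SEED))
filt <- filter_days(sim$data)

cat(sprintf("generated %d days from %d participants; %d days excluded:\n",
            nrow(sim$data), length(unique(sim$data$pid)),
            nrow(filt$exclusions)))
print(table(filt$exclusions$reason))
days <- table(filt$data$pid)
cat(sprintf("analyzed: %d days, %d participants, %.2f days/participant (range %d-%d)\n",
            nrow(filt$data), length(days), mean(days), min(days), max(days)))

comp_h <- composition_matrix(filt$data) / 60
outcomes <- c("valence", "energetic_arousal", "calmness", "working_memory")
desc <- rbind(
  data.frame(variable = paste0(colnames(comp_h), "_h"),
             mean = colMeans(comp_h), sd = apply(comp_h, 2, sd)),
  data.frame(variable = outcomes,
             mean = sapply(filt$data[outcomes], mean, na.rm = TRUE),
             sd = sapply(filt$data[outcomes], sd, na.rm = TRUE)),
  data.frame(variable = "wear_h", mean = mean(filt$data$wear_h),
             sd = sd(filt$data$wear_h)))
rownames(desc) <- NULL
print(desc, digits = 3)

write.csv(sim$data, "results/synthetic_cohort_raw.csv", row.names = FALSE)
write.csv(filt$data, "results/synthetic_cohort_analyzed.csv", row.names = FALSE)
write.csv(filt$exclusions, "results/exclusion_log.csv", row.names = FALSE)
write.csv(desc, "results/descriptives.csv", row.names = FALSE)
cat("wrote results/synthetic_cohort_{raw,analyzed}.csv, exclusion_log.csv, descriptives.csv\n")
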