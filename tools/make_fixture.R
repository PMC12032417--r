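# Regenerate the small synthetic fixture shipped under inst/extdata.
# 20 participants x 6 monitored days, all days valid (no wear/sleep/walk
# exclusions, no missing outcomes), workweek calendar. Seed recorded here;
# the file is bit-reproducible from this script.
# Run from the repository root: Rscript tools/make_fixture.R

library(coda24)

cfg <- generator_config(n_participants = 20, days_mean = 6, days_sd = 0.01,
                        days_range = c(6, 6), nonwear_mean_h = 2.0,
                        nonwear_sd_h = 0.35, p_sleep_zero = 0, p_no_walk = 0,
                        missing_outcome_rate = 0, seed = 2024)
d <- simulate_emia(cfg)$data
stopifnot(nrow(filter_days(d)$exclusions) == 0)

num <- vapply(d, is.numeric, logical(1))
d[num] <- lapply(d[num], function(x) round(x, 3))
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.csv(d, "inst/extdata/ema_days_synthetic_small.csv", row.names = FALSE,
          quote = FALSE)
cat("wrote", nrow(d), "rows;",
    file.size("inst/extdata/ema_days_synthetic_small.csv"), "bytes\n")
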