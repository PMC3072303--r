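#!/usr/bin/env Rscript

# Stage 1: simulate the development data.
#
# Generates a synthetic whole-blood cohort (113 genes, 640 subjects, planted
# cell-type co-expression and sex-dependent CAD effects), passes it through
# the RT-PCR triplicate-measurement model, and writes the expression matrix
# and sample sheet that the downstream stages read.

suppressMessages(library(cadscore))

seed <- 101L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- generate_cohort(cfg)

# RT-PCR measurement: triplicate wells, median-aggregated
expr_pcr <- simulate_pcr_panel(sim$expr, replicate_sd = 0.15,
                               outlier_rate = 0.01, seed = seed + 1L)

write_expression(expr_pcr, "results/cohort_expression.tsv")
write_samples(sim$samples, "results/cohort_samples.csv")
utils::write.table(sim$truth, "results/cohort_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cfg_echo <- run_config(seed = seed)
write_config_echo(cfg_echo, "results/run_config.json")

cat(sprintf("cohort: %d genes x %d samples, %d cases / %d controls\n",
            nrow(expr_pcr), ncol(expr_pcr),
            sum(sim$samples$status == "case"),
            sum(sim$samples$status == "control")))
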