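#!/usr/bin/env Rscript
# Bulk cleavage kinetics: mono-exponential fits per replicate and the
# fold change between the optimized variant and the wild-type-like enzyme.

suppressPackageStartupMessages(library(aurbt))
dir.create("results/cleavage", recursive = TRUE, showWarnings = FALSE)

wt <- fit_monoexp(read_table_tsv("results/cleavage_wt.tsv"))
var <- fit_monoexp(read_table_tsv("results/cleavage_variant.tsv"))

cat("wild-type-like enzyme:\n"); print(wt)
cat("optimized variant:\n"); print(var)

fc <- rate_fold_change(var, wt)
cat(sprintf("\nfold change in kobs: %.1f +/- %.1f\n", fc$fold, fc$sd))

out <- rbind(
  data.frame(sample = "wt", A = wt$A_mean, sd_A = wt$A_sd,
             kobs_per_min = wt$kobs_mean, sd_kobs = wt$kobs_sd,
             n_reps = wt$n_reps),
  data.frame(sample = "variant", A = var$A_mean, sd_A = var$A_sd,
             kobs_per_min = var$kobs_mean, sd_kobs = var$kobs_sd,
             n_reps = var$n_reps))
write_table_tsv(out, "results/cleavage/fits.tsv")
jsonlite::write_json(list(fold = fc$fold, sd = fc$sd),
                     "results/cleavage/fold_change.json",
                     auto_unbox = TRUE, digits = NA)
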