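#!/usr/bin/env Rscript

# Stage 5 — stem WSC remobilisation statistics.
#
# Summarises the phenotype table: peak timing per treatment, the 12->22 DAA
# decline and daily rate per line under water deficit, relative slowdown
# versus the parent, and the correlation of grain weight with the
# remobilisation rate across lines and replicate-stage observations.

library(hibdel)

pheno <- read_wsc_phenotype(system.file("extdata",
                                        "wsc_phenotype_synthetic.csv",
                                        package = "hibdel"))

shift <- find_peak(wsc_series(pheno, "Chara", "well_watered")) -
  find_peak(wsc_series(pheno, "Chara", "water_deficit"))
message(sprintf("water deficit moves the WSC peak %d days earlier", shift))

tab <- remobilisation_table(pheno, parent = "Chara",
                            treatment = "water_deficit", window = c(12, 22))
dir.create("results", showWarnings = FALSE)
readr::write_tsv(tab, "results/wsc_remobilisation.tsv", na = "")
print(as.data.frame(tab[, c("line", "peak_daa", "wsc_start", "wsc_end",
                            "decline", "rate", "slowdown_vs_parent_pct")]))

# grain weight at 32 DAA against the per-line remobilisation rate
final <- pheno[pheno$treatment == "water_deficit" & pheno$daa == 32, ]
final <- final[match(tab$line, final$line), ]
ct <- wsc_correlate(tab$rate, final$grain_weight_g)
message(sprintf("grain weight vs remobilisation rate: r = %.2f (p = %.3f, n = %d lines)",
                ct$r, ct$p, ct$n))
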