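#!/usr/bin/env Rscript

# Stage 4 — genes inside the deletion intervals.
#
# Queries the bundled synthetic 6B gene annotation against the mapped
# intervals, classifies gene function by keyword and screens non-target
# genes for negligible expression relative to the fructan 1-exohydrolase
# reference at the reproductive stage. Also reproduces the three published
# interval sizes from the published flanking-marker table.

library(hibdel)

# published flanking markers: the three interval sizes
mk <- read_marker_map(system.file("extdata", "feh_mutant_markers.csv",
                                  package = "hibdel"))
flanks <- list(`6A` = c("wsnp_CAP8_c6680_3136899", "BobWhite_c44549_83"),
               `6B` = c("BS00074183_51", "tplb0055h14_483"),
               `6D` = c("D_GBQ4KXB01B5NHZ_336", "Kukri_c5531_358"))
for (chrom in names(flanks)) {
  iv <- make_interval(mk[mk$name %in% flanks[[chrom]], ])
  message(sprintf("%s deletion: %s..%s = %s bp", chrom,
                  format(iv$start, big.mark = ","),
                  format(iv$end, big.mark = ","),
                  format(iv$size, big.mark = ",")))
}

# gene content of the 6B interval
genes <- read_gene_annotation(system.file("extdata", "genes_6B_synthetic.gff3",
                                          package = "hibdel"))
expr <- read_expression(system.file("extdata", "expression_6B_synthetic.tsv",
                                    package = "hibdel"))
iv6b <- tibble::tibble(chromosome = "6B", start = 54419374, end = 59295496)
ann <- annotate_intervals(iv6b, genes, expression = expr,
                          reference_genes = list(`6B` = "TraesCS6B02G080750"),
                          stage = "reproductive")
dir.create("results", showWarnings = FALSE)
readr::write_tsv(ann, "results/interval_genes_6B.tsv", na = "")
message(sprintf("6B interval: %d genes (%d HC); classes: %s", nrow(ann),
                sum(ann$confidence == "HC"),
                paste(names(table(ann$functional_class)),
                      table(ann$functional_class), collapse = ", ")))
message(sprintf("non-target genes with non-negligible expression: %d",
                sum(!ann$negligible, na.rm = TRUE)))
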