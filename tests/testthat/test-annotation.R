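gff_path <- system.file("extdata", "genes_6B_synthetic.gff3", package = "hibdel")
expr_path <- system.file("extdata", "expression_6B_synthetic.tsv",
                         package = "hibdel")
iv6b <- list(chromosome = "6B", start = 54419374, end = 59295496)

brute_overlap <- function(interval, genes) {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    keep[i] <- genes$chromosome[i] == interval$chromosome &&
      genes$start[i] <= interval$end && genes$end[i] >= interval$start
  }
  sort(genes$gene_id[keep])
}

test_that("interval gene queries agree with a brute-force overlap scan", {
  genes <- read_gene_annotation(gff_path)
  expect_equal(nrow(genes), 10)

  hit <- genes_in_interval(iv6b, genes)
  expect_equal(sort(hit$gene_id), brute_overlap(iv6b, genes))
  expect_equal(nrow(hit), 8)
  # 1-bp inclusive boundary: SYNB6G000100 ends just inside the interval start
  expect_true("SYNB6G000100" %in% hit$gene_id)
  expect_false("SYNB6G000400" %in% hit$gene_id)

  # randomised intervals against the brute-force oracle
  set.seed(1)
  for (i in 1:250) {
    a <- sample(5.3e7:6.0e7, 1)
    q <- list(chromosome = "6B", start = a, end = a + sample(1e3:5e6, 1))
    expect_equal(sort(genes_in_interval(q, genes)$gene_id),
                 brute_overlap(q, genes))
  }

  expect_equal(nrow(genes_in_interval(iv6b, genes, hc_only = TRUE)), 7)
  expect_warning(out <- genes_in_interval(list(chromosome = "1A", start = 1,
                                               end = 2), genes), "absent")
  expect_equal(nrow(out), 0)
})

test_that("functional classification follows the ordered keyword rules", {
  expect_equal(classify_function("Fructan 1-exohydrolase w3"), "hydrolase")
  expect_equal(classify_function("glycoside hydrolase family 32"), "hydrolase")
  expect_equal(classify_function("DNA ligase 1"), "ligase")
  expect_equal(classify_function("Cytochrome P450 oxidoreductase"),
               "oxidoreductase")
  expect_equal(classify_function("Glycosyltransferase family 61 protein"),
               "transferase")
  expect_equal(classify_function(""), "uncharacterised")
  expect_equal(classify_function(NA), "uncharacterised")
  expect_equal(classify_function("uncharacterized protein"), "uncharacterised")
  expect_equal(classify_function("cell wall structural protein"), "other")

  # class counts on the fixture equal a brute-force keyword scan
  genes <- read_gene_annotation(gff_path)
  got <- table(classify_function(genes$description))
  kw <- default_function_keywords()
  manual <- vapply(genes$description, function(d) {
    d <- tolower(d)
    if (grepl("uncharacteri", d)) return("uncharacterised")
    for (cl in names(kw)) if (grepl(kw[[cl]], d)) return(cl)
    "other"
  }, character(1))
  expect_equal(as.list(got), as.list(table(manual)))
})

test_that("expression negligibility is a ratio test with monotone threshold", {
  expr <- read_expression(expr_path)
  ref <- "TraesCS6B02G080750"
  expect_true(negligible_expression("not_in_table", ref, expr))
  expect_true(negligible_expression("TraesCS6B02G080700", ref, expr,
                                    stage = "reproductive"))
  expect_false(negligible_expression("TraesCS6B02G080800", ref, expr,
                                     stage = "reproductive", ratio_threshold = 0.1))
  expect_false(negligible_expression(ref, ref, expr))       # ratio 1 >= threshold
  expect_error(negligible_expression("x", "no_such_ref", expr), "absent")

  # stage filtering changes the reference scale
  expect_true(negligible_expression("SYNB6G000300", ref, expr,
                                    stage = "reproductive"))
  expect_false(negligible_expression("SYNB6G000300", ref, expr,
                                     stage = "vegetative"))

  # monotone in ratio_threshold
  gene <- "TraesCS6B02G080800"
  flags <- vapply(c(0.01, 0.1, 0.2, 0.5), function(t) {
    negligible_expression(gene, ref, expr, stage = "reproductive",
                          ratio_threshold = t)
  }, logical(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("interval annotation combines overlap, classes and the screen", {
  genes <- read_gene_annotation(gff_path)
  expr <- read_expression(expr_path)
  iv <- tibble::tibble(chromosome = "6B", start = 54419374, end = 59295496)
  ann <- annotate_intervals(iv, genes, expression = expr,
                            reference_genes = list(`6B` = "TraesCS6B02G080750"),
                            stage = "reproductive")
  expect_equal(nrow(ann), 8)
  expect_true(ann$is_reference[ann$gene_id == "TraesCS6B02G080750"])
  expect_equal(ann$functional_class[ann$gene_id == "TraesCS6B02G080750"],
               "hydrolase")
  scr <- ann[!ann$is_reference & !is.na(ann$negligible), ]
  expect_false(all(scr$negligible))   # one glycoside hydrolase is above 10%
  expect_true(sum(!scr$negligible) == 1)
})
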