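#' Read gene features from a GFF3 annotation
#'
#' Thin wrapper over `rtracklayer::import` keeping `gene` features only.
#' Coordinates stay 1-based inclusive (the GFF3 convention, shared by the
#' package's interval coordinates).
#'
#' @param path GFF3 file.
#' @param confidence_key Attribute key holding the HC/LC gene-model
#'   confidence class (annotation releases differ; default
#'   `"confidence"`).
#' @param description_key Attribute key holding the functional description.
#' @return Tibble: `gene_id`, `chromosome`, `start`, `end`, `confidence`,
#'   `description`.
#' @export
read_gene_annotation <- function(path, confidence_key = "confidence",
                                 description_key = "description") {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  meta <- S4Vectors::mcols(gr)
  pick <- function(key) {
    if (key %in% names(meta)) as.character(meta[[key]]) else NA_character_
  }
  tibble::tibble(
    gene_id = as.character(meta$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    confidence = pick(confidence_key),
    description = pick(description_key))
}

#' Genes overlapping a deletion interval
#'
#' Returns annotation genes on the interval's chromosome whose 1-based
#' inclusive span overlaps the interval by at least 1 bp (a gene ending
#' exactly at `interval$start` is included), sorted by start.
#'
#' @param interval One-row interval (list or tibble with `chromosome`,
#'   `start`, `end`).
#' @param annotation Gene tibble from [read_gene_annotation()].
#' @param hc_only Keep high-confidence (`"HC"`) gene models only.
#' @return Subset of `annotation`, sorted by `start`. Empty (with a
#'   warning) when the chromosome is absent from the annotation.
#' @export
genes_in_interval <- function(interval, annotation, hc_only = FALSE) {
  g <- annotation[annotation$chromosome == interval$chromosome, ]
  if (nrow(g) == 0) {
    warning("chromosome '", interval$chromosome,
            "' absent from the annotation")
    return(g)
  }
  if (hc_only) g <- g[!is.na(g$confidence) & g$confidence == "HC", ]
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(interval$start, interval$end),
    IRanges::IRanges(g$start, g$end))
  g <- g[S4Vectors::subjectHits(hits), ]
  g[order(g$start), ]
}

#' Ordered keyword rules for functional classification
#'
#' First-match-wins regexes over the (lower-cased) gene description,
#' covering the four enzyme classes observed among deletion-interval
#' genes. Extend or reorder to taste and pass to [classify_function()].
#'
#' @return Named character vector of regexes, in matching order.
#' @export
default_function_keywords <- function() {
  c(hydrolase = "hydrolase|hydrolysis|glycosidase|glucanase|amylase|protease|peptidase",
    ligase = "ligase",
    oxidoreductase = "oxidoreductase|oxidase|reductase|dehydrogenase|peroxidase",
    transferase = "transferase|kinase")
}

#' Classify a gene's function from its description
#'
#' Empty, missing or explicitly uncharacterised descriptions give
#' `"uncharacterised"`; otherwise the first matching keyword class wins;
#' described genes matching no class are `"other"`.
#'
#' @param description Character vector of free-text descriptions.
#' @param keywords Ordered named regex vector
#'   ([default_function_keywords()]).
#' @return Character vector of class labels.
#' @export
classify_function <- function(description, keywords = default_function_keywords()) {
  d <- tolower(trimws(ifelse(is.na(description), "", description)))
  out <- rep("other", length(d))
  unchar <- d == "" | grepl("uncharacteri[sz]ed|unknown function", d)
  for (cl in rev(names(keywords)))
    out[grepl(keywords[[cl]], d)] <- cl
  out[unchar] <- "uncharacterised"
  out
}

#' Negligible-expression screen against a reference gene
#'
#' A non-target gene is considered expressionally negligible when its
#' maximum abundance over the (optionally stage-filtered) samples is below
#' `ratio_threshold` times the reference gene's maximum over the same
#' samples. A gene absent from the table has zero recorded expression and
#' is negligible by definition.
#'
#' @param gene_id Gene to screen.
#' @param reference_gene_id Reference (e.g. the targeted gene); must be
#'   present in the table.
#' @param expression Tibble `gene_id`, `sample`, `stage`, `tpm`.
#' @param stage Optional stage label filter (e.g. `"reproductive"`).
#' @param ratio_threshold Fraction of the reference maximum (default 0.1).
#' @return `TRUE` when negligible.
#' @export
negligible_expression <- function(gene_id, reference_gene_id, expression,
                                  stage = NULL, ratio_threshold = 0.1) {
  e <- expression
  if (!is.null(stage)) e <- e[e$stage %in% stage, ]
  ref <- e$tpm[e$gene_id == reference_gene_id]
  if (length(ref) == 0)
    stop("reference gene '", reference_gene_id,
         "' absent from the expression table", call. = FALSE)
  x <- e$tpm[e$gene_id == gene_id]
  if (length(x) == 0) return(TRUE)
  max(x) < ratio_threshold * max(ref)
}

#' Annotate the genes inside deletion intervals
#'
#' For each interval: overlap genes, classify their function, and (when an
#' expression table and a per-chromosome reference gene are given) screen
#' non-target genes for negligible expression.
#'
#' @param intervals Intervals tibble ([map_intervals()]).
#' @param annotation Gene tibble ([read_gene_annotation()]).
#' @param expression Optional expression tibble (see
#'   [negligible_expression()]).
#' @param reference_genes Optional named list `chromosome -> gene_id` of
#'   the targeted gene per interval.
#' @param stage Stage filter for the expression screen.
#' @param ratio_threshold Expression-negligibility threshold.
#' @param hc_only Restrict to high-confidence gene models.
#' @return Tibble of interval genes with `functional_class`,
#'   `is_reference` and `negligible` columns.
#' @export
annotate_intervals <- function(intervals, annotation, expression = NULL,
                               reference_genes = NULL, stage = NULL,
                               ratio_threshold = 0.1, hc_only = FALSE) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    g <- genes_in_interval(iv, annotation, hc_only = hc_only)
    if (nrow(g) == 0) return(NULL)
    g$interval_chromosome <- iv$chromosome
    g$functional_class <- classify_function(g$description)
    ref <- reference_genes[[iv$chromosome]]
    g$is_reference <- !is.null(ref) & g$gene_id %in% ref
    g$negligible <- NA
    if (!is.null(expression) && !is.null(ref)) {
      g$negligible <- vapply(g$gene_id, negligible_expression, logical(1),
                             reference_gene_id = ref, expression = expression,
                             stage = stage, ratio_threshold = ratio_threshold)
      g$negligible[g$is_reference] <- NA
    }
    g
  })
  dplyr::bind_rows(out)
}
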