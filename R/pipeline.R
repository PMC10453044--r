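#' Pipeline configuration
#'
#' Bundles the stage configurations and sample identities for
#' [run_pipeline()]. Either a simulation config (everything is generated)
#' or paths to an existing marker map and intensity table must be given.
#'
#' @param out_dir Run directory (created; one directory per invocation).
#' @param sim Optional [sim_config()] for the simulate stage.
#' @param marker_path,intensity_path Input files, used when `sim` is
#'   `NULL`.
#' @param parent Euploid parent sample id.
#' @param mutants Character vector of mutant sample ids.
#' @param f1 Optional named vector mapping mutant id -> backcross F1 id.
#' @param parent_bc Optional backcross parent-stock sample id.
#' @param panel_prefix Prefix selecting reference-panel sample ids.
#' @param caller A [caller_config()].
#' @param mapper A [mapper_config()].
#' @param gff_path,expression_path Optional annotation inputs.
#' @param reference_genes Optional named list chromosome -> target gene id.
#' @param wsc_path Optional phenotype CSV for the WSC stage.
#' @param wsc_parent,wsc_treatment,wsc_window WSC stage options.
#' @param seed Seed recorded in the manifest (the simulate stage uses the
#'   seed inside `sim`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = NULL, marker_path = NULL,
                            intensity_path = NULL, parent = "Chara",
                            mutants = NULL, f1 = NULL, parent_bc = NULL,
                            panel_prefix = "HIB_",
                            caller = caller_config(),
                            mapper = mapper_config(),
                            gff_path = NULL, expression_path = NULL,
                            reference_genes = NULL, wsc_path = NULL,
                            wsc_parent = "Chara",
                            wsc_treatment = "water_deficit",
                            wsc_window = c(12, 22), seed = 1L) {
  if (is.null(sim) && (is.null(marker_path) || is.null(intensity_path)))
    stop("either `sim` or both `marker_path` and `intensity_path` are required",
         call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `sim`,
#' `caller` and `mapper` sub-maps are passed to their constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$caller)) y$caller <- do.call(caller_config, y$caller)
  if (!is.null(y$mapper)) y$mapper <- do.call(mapper_config, y$mapper)
  if (!is.null(y$wsc_window)) y$wsc_window <- as.numeric(y$wsc_window)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load) -> call -> map -> annotate -> wsc, writing
#' each stage's outputs under the run directory together with a
#' machine-readable `manifest.json` (package version, seed, configuration
#' hash, stage status and output files). Rerunning with an identical
#' configuration reproduces identical call and interval outputs.
#'
#' @param config A [pipeline_config()] or path to its YAML serialisation.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  stages <- list()
  outputs <- list()

  # -- simulate / load ------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_experiment(config$sim)
    markers <- sim$markers
    intensities <- sim$intensities
    write_marker_map(markers, p("markers.csv"))
    write_intensities(intensities, p("intensities.csv"))
    write_truth(sim$truth, p("truth.json"))
    if (is.null(config$mutants))
      config$mutants <- unique(
        sim$truth$deletions$sample_id[sim$truth$deletions$zygosity == "hom"])
    if (is.null(config$f1)) {
      f1s <- sim$truth$deletions[sim$truth$deletions$zygosity == "het", ]
      config$f1 <- setNames(f1s$sample_id, sub("^f1_", "mut_", f1s$sample_id))
    }
    if (is.null(config$parent_bc) &&
        "Chara_BC" %in% intensities$sample_id)
      config$parent_bc <- "Chara_BC"
    stages$simulate <- "done"
  } else {
    markers <- read_marker_map(config$marker_path)
    intensities <- read_intensities(config$intensity_path)
    stages$simulate <- "skipped (inputs supplied)"
  }

  # -- call + map, one mutant at a time -------------------------------
  if (length(config$mutants) > 0) {
    all_calls <- list()
    all_intervals <- list()
    for (m in config$mutants) {
      calls <- call_deletions(intensities, markers, parent = config$parent,
                              sample = m, f1 = unname(config$f1[m]),
                              panel_prefix = config$panel_prefix,
                              parent_bc = config$parent_bc,
                              config = config$caller)
      write_calls(calls, p(paste0("calls_", m, ".csv")),
                  p(paste0("biotype_", m, ".csv")))
      iv <- map_intervals(calls, markers, config$mapper)
      iv <- tibble::tibble(sample_id = rep(m, nrow(iv)), iv)
      all_calls[[m]] <- calls
      all_intervals[[m]] <- iv
    }
    intervals <- dplyr::bind_rows(all_intervals)
    write_intervals(intervals, p("intervals.csv"), p("intervals.bed"))
    stages$call <- "done"
    stages$map <- "done"
    outputs$calls <- all_calls
    outputs$intervals <- intervals
  } else {
    stages$call <- "skipped (no mutants)"
    stages$map <- "skipped (no mutants)"
    intervals <- NULL
  }

  # -- annotate -------------------------------------------------------
  if (!is.null(config$gff_path) && !is.null(intervals) && nrow(intervals) > 0) {
    ann <- read_gene_annotation(config$gff_path)
    expr <- if (is.null(config$expression_path)) NULL
            else read_expression(config$expression_path)
    genes <- annotate_intervals(intervals, ann, expression = expr,
                                reference_genes = config$reference_genes,
                                stage = "reproductive")
    readr::write_tsv(genes, p("interval_genes.tsv"), na = "")
    outputs$genes <- genes
    stages$annotate <- "done"
  } else stages$annotate <- "skipped"

  # -- wsc ------------------------------------------------------------
  if (!is.null(config$wsc_path)) {
    pheno <- read_wsc_phenotype(config$wsc_path)
    wsc <- remobilisation_table(pheno, parent = config$wsc_parent,
                                treatment = config$wsc_treatment,
                                window = config$wsc_window)
    readr::write_tsv(wsc, p("wsc_remobilisation.tsv"), na = "")
    outputs$wsc <- wsc
    stages$wsc <- "done"
  } else stages$wsc <- "skipped"

  manifest <- list(package = "hibdel",
                   version = as.character(utils::packageVersion("hibdel")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = stages,
                   files = list.files(config$out_dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(manifest = manifest, outputs = outputs))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}
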