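#' Simulate a full array experiment with ground truth
#'
#' Generates NormTheta/NormR observations for:
#' \itemize{
#'   \item the euploid parent stock used to derive the mutants (`Chara`);
#'   \item a second parent seed stock used for backcrossing (`Chara_BC`),
#'     carrying discordant "biotype" genotypes at a `biotype_rate` fraction
#'     of markers (the primary-site allele is swapped);
#'   \item per deletion spec, a homozygous mutant (`mut_<subgenome>`, dosage
#'     0 at sites inside the deletion) and a backcross F1
#'     (`f1_<subgenome>`, dosage 1 inside: one intact haplotype from the
#'     backcross stock, one deleted haplotype from the mutant);
#'   \item `n_panel` unrelated euploid-background panel samples
#'     (`HIB_001`, ...).
#' }
#'
#' @param config A [sim_config()].
#' @param markers Optional pre-built marker panel; defaults to
#'   [build_marker_panel()] under the config's seed.
#' @return A list of class `hib_simulation`: `markers`, `intensities`
#'   (long tibble `sample_id`, `marker_name`, `norm_theta`, `norm_r`),
#'   `truth` (deletions per simulated sample, biotype marker names, seed)
#'   and `config`.
#' @export
simulate_experiment <- function(config, markers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(markers)) markers <- build_marker_panel(config)
  withr::with_seed(config$seed + 1L, .simulate(config, markers))
}

.simulate <- function(cfg, markers) {
  sites <- marker_sites(markers)
  nm <- nrow(markers)
  mfac <- factor(sites$name, levels = markers$name)
  is_primary <- sites$subgenome == sites$chromosome

  biotype <- markers$name[runif(nm) < cfg$biotype_rate]
  swapped <- sites$allele
  swap_at <- is_primary & sites$name %in% biotype
  swapped[swap_at] <- ifelse(sites$allele[swap_at] == "A", "B", "A")

  # channel sums for one haplotype (copies in {0,1} per site)
  hap_sums <- function(copies, allele) {
    w <- sites$gain * copies
    a <- rowsum(w * (allele == "A"), mfac)[, 1]
    b <- rowsum(w * (allele == "B"), mfac)[, 1]
    cbind(a, b)
  }
  inside <- function(del) {
    sites$subgenome == del$subgenome &
      sites$position >= del$start & sites$position <= del$end
  }

  ones <- rep(1, nrow(sites))
  hap_parent <- hap_sums(ones, sites$allele)
  hap_bc     <- hap_sums(ones, swapped)

  profiles <- list(Chara = 2 * hap_parent, Chara_BC = 2 * hap_bc)
  truth_rows <- list()
  for (del in cfg$deletions) {
    keep <- 1 - inside(del)
    hap_mut <- hap_sums(keep, sites$allele)
    mut_id <- paste0("mut_", del$subgenome)
    f1_id <- paste0("f1_", del$subgenome)
    profiles[[mut_id]] <- 2 * hap_mut
    profiles[[f1_id]] <- hap_mut + hap_bc
    truth_rows[[mut_id]] <- tibble::tibble(
      sample_id = c(mut_id, f1_id), subgenome = del$subgenome,
      start = del$start, end = del$end, zygosity = c("hom", "het"))
  }
  for (i in seq_len(cfg$n_panel))
    profiles[[sprintf("HIB_%03d", i)]] <- 2 * hap_parent

  ids <- names(profiles)
  a <- unlist(lapply(profiles, function(p) p[, 1]), use.names = FALSE)
  b <- unlist(lapply(profiles, function(p) p[, 2]), use.names = FALSE)
  out <- .theta_r(a, b, cfg$noise_sd)
  obs <- tibble::tibble(sample_id = rep(ids, each = nm),
                        marker_name = rep.int(markers$name, length(ids)),
                        norm_theta = out$norm_theta, norm_r = out$norm_r)

  structure(
    list(markers = markers,
         intensities = obs,
         truth = list(deletions = dplyr::bind_rows(truth_rows),
                      biotype_markers = biotype, seed = cfg$seed),
         config = cfg),
    class = "hib_simulation")
}

#' @export
print.hib_simulation <- function(x, ...) {
  cat("Synthetic array experiment:", nrow(x$markers), "markers,",
      length(unique(x$intensities$sample_id)), "samples,",
      nrow(x$truth$deletions), "true deletion records\n")
  invisible(x)
}
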