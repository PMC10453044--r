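#' Simulation configuration for a synthetic 90K-style array experiment
#'
#' Defines the study conditions under which the synthetic-data module
#' emulates an Infinium-style genotyping run on allohexaploid wheat: a
#' marker panel whose probes hybridise to one, two or three homoeologous
#' sites across the 6A/6B/6D subgenomes, a euploid parent, one homozygous
#' deletion mutant plus one heterozygous parent-x-mutant F1 per specified
#' deletion, and a reference panel of unrelated euploid-background mutants.
#'
#' Defaults mirror the mapped experiment: three subgenomes of 60 Mb, the
#' three deletion intervals recovered on 6A/6B/6D, a 96-line reference
#' panel, per-channel Gaussian noise of 0.05 signal units and a per-allele
#' gain of 1 (so a euploid two-copy single-site marker has NormR = 2).
#'
#' @param n_markers Number of markers on the panel (total over subgenomes).
#' @param subgenomes Labels of the subgenomes.
#' @param chrom_length Length (bp) of each model chromosome.
#' @param multisite_fraction Probability that a probe hybridises to more
#'   than one subgenome.
#' @param site_count_probs Probabilities of 2 vs 3 sites for a multi-site
#'   probe. Heavily weighted towards 3: homoeologue divergence across a
#'   50-mer probe is within hybridisation tolerance, so a probe that
#'   cross-hybridises at all almost always binds all three homoeoloci;
#'   two-site probes correspond to the minority of loci where one
#'   homoeolocus is diverged or absent (e.g. tetraploid-derived loci with
#'   no D copy).
#' @param gain Signal units contributed per allele copy at a site.
#' @param noise_sd Per-channel Gaussian noise SD, signal units.
#' @param null_floor NormR below which an observation is a null
#'   (no-fluorescence) allele, in units where `gain = 1`.
#' @param biotype_rate Fraction of markers at which the backcross parent
#'   stock carries a discordant ("biotype") genotype relative to the
#'   parent stock used to make the mutants.
#' @param homoeo_jitter Maximum offset (bp) of a homoeologous site from
#'   the probe's primary position.
#' @param n_panel Number of unrelated reference-panel samples.
#' @param deletions List of [true_deletion()] specs; each produces one
#'   homozygous mutant and one heterozygous backcross F1.
#' @param seed Integer seed; all randomness in the generator derives from
#'   it.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_experiment()], [build_marker_panel()]
#' @export
sim_config <- function(n_markers = 900,
                       subgenomes = c("6A", "6B", "6D"),
                       chrom_length = 6e7,
                       multisite_fraction = 0.7,
                       site_count_probs = c(`2` = 0.05, `3` = 0.95),
                       gain = 1,
                       noise_sd = 0.05,
                       null_floor = 0.2,
                       biotype_rate = 0.02,
                       homoeo_jitter = 2e6,
                       n_panel = 96,
                       deletions = default_deletions(),
                       seed = 1L) {
  if (n_markers < 1) stop("`n_markers` must be >= 1", call. = FALSE)
  for (p in c(multisite_fraction, biotype_rate)) {
    if (is.na(p) || p < 0 || p > 1)
      stop("fractions must be probabilities in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  if (length(subgenomes) < 1) stop("at least one subgenome", call. = FALSE)
  stopifnot(length(site_count_probs) == 2, all(site_count_probs >= 0))
  deletions <- lapply(deletions, function(d) {
    if (!inherits(d, "true_deletion")) d <- do.call(true_deletion, d)
    if (!d$subgenome %in% subgenomes)
      stop("deletion subgenome '", d$subgenome, "' not in the panel", call. = FALSE)
    if (d$start < 1 || d$end > chrom_length)
      stop("deletion [", d$start, ", ", d$end, "] outside chromosome bounds",
           call. = FALSE)
    d
  })
  structure(
    list(n_markers = as.integer(n_markers), subgenomes = subgenomes,
         chrom_length = chrom_length,
         multisite_fraction = multisite_fraction,
         site_count_probs = site_count_probs / sum(site_count_probs),
         gain = gain, noise_sd = noise_sd, null_floor = null_floor,
         biotype_rate = biotype_rate, homoeo_jitter = homoeo_jitter,
         n_panel = as.integer(n_panel), deletions = deletions,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Ground-truth deletion specification
#'
#' @param subgenome Subgenome carrying the deletion.
#' @param start,end Deletion breakpoints, bp (1-based, `start < end`).
#' @param zygosity `"hom"` (dosage 0 inside) for the mutant itself; the
#'   matching backcross F1 is always simulated at `"het"` (dosage 1).
#' @return A `true_deletion` list.
#' @export
true_deletion <- function(subgenome, start, end, zygosity = c("hom", "het")) {
  zygosity <- match.arg(zygosity)
  if (!(start < end)) stop("deletion must have start < end", call. = FALSE)
  structure(list(subgenome = subgenome, start = start, end = end,
                 zygosity = zygosity),
            class = "true_deletion")
}

#' The three default deletion intervals (6A, 6B, 6D)
#'
#' The homozygous intervals recovered by flanking-marker mapping in the
#' source experiment, used as the generator's default ground truth.
#'
#' @return List of three [true_deletion()] specs.
#' @export
default_deletions <- function() {
  list(true_deletion("6A", 12836428, 41083389),
       true_deletion("6B", 54419374, 59295496),
       true_deletion("6D", 28682554, 30283308))
}
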