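#' Run-segmentation options for interval mapping
#'
#' @param gap_max Maximum bp gap between consecutive flagged markers inside
#'   one run. `NULL` (default) sets it at map time to `gap_mult` times the
#'   median inter-marker spacing of the chromosome. Under near-uniform
#'   marker placement inter-marker gaps are approximately exponential, so a
#'   multiple of the median spacing bounds the chance of splitting a
#'   contiguous deletion; 20x gives a per-gap split probability of about
#'   `exp(-20 * log(2)) ~ 1e-6` while still separating regions on opposite
#'   chromosome arms.
#' @param gap_mult Multiplier used when `gap_max` is `NULL`.
#' @param min_markers Minimum flagged markers per run (>= 2).
#' @param target_loci Optional named list `chromosome -> c(start, end)` of
#'   loci of interest (e.g. the targeted gene), tested for containment.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(gap_max = NULL, gap_mult = 20, min_markers = 3,
                          target_loci = NULL) {
  if (!is.null(gap_max) && gap_max <= 0)
    stop("`gap_max` must be > 0", call. = FALSE)
  if (min_markers < 2) stop("`min_markers` must be >= 2", call. = FALSE)
  structure(list(gap_max = gap_max, gap_mult = gap_mult,
                 min_markers = as.integer(min_markers),
                 target_loci = target_loci),
            class = "mapper_config")
}

#' Find high-density runs of flagged markers
#'
#' Per chromosome, flagged markers sorted by position are split wherever
#' the gap between consecutive flagged markers exceeds `gap_max`; maximal
#' groups with at least `min_markers` members become candidate runs.
#' Unflagged markers lying inside a run's span are recorded as discordant
#' support (they do not split the run: a probe can fail to shift when a
#' paralogous site masks the dosage change).
#'
#' @param calls Calls tibble with `marker_name`, `chromosome`,
#'   `span_start`, `span_end`, `flagged`.
#' @param config A [mapper_config()].
#' @return Tibble of runs: `run_id`, `chromosome`, `n_support`,
#'   `marker_names` (list), `discordant` (list of unflagged markers inside
#'   the span).
#' @export
find_runs <- function(calls, config = mapper_config()) {
  runs <- list()
  for (chrom in unique(calls$chromosome)) {
    cc <- calls[calls$chromosome == chrom, ]
    cc <- cc[order(cc$span_start), ]
    fl <- cc[cc$flagged, ]
    if (nrow(fl) == 0) next
    gap_max <- config$gap_max
    if (is.null(gap_max)) {
      spacing <- diff(cc$span_start)
      gap_max <- config$gap_mult * max(median(spacing), 1)
    }
    grp <- cumsum(c(0, diff(fl$span_start) > gap_max))
    for (g in unique(grp)) {
      mem <- fl[grp == g, ]
      if (nrow(mem) < config$min_markers) next
      disc <- cc$marker_name[!cc$flagged &
                               cc$span_start >= min(mem$span_start) &
                               cc$span_start <= max(mem$span_start)]
      runs[[length(runs) + 1L]] <- tibble::tibble(
        chromosome = chrom, n_support = nrow(mem),
        marker_names = list(mem$marker_name), discordant = list(disc))
    }
  }
  out <- dplyr::bind_rows(runs)
  if (nrow(out) == 0)
    return(tibble::tibble(run_id = integer(), chromosome = character(),
                          n_support = integer(), marker_names = list(),
                          discordant = list()))
  tibble::tibble(run_id = seq_len(nrow(out)), out)
}

#' Deletion interval from a run's flanking markers
#'
#' The interval starts at the `span_start` of the first (lowest-position)
#' flanking marker and ends at the `span_end` of the last flanking marker
#' (the member with the largest `span_start`); its size is the plain
#' difference `end - start` in bp, the convention under which the reported
#' flanking coordinates reproduce the reported sizes exactly.
#'
#' @param run_markers Marker/call rows belonging to one run (needs
#'   `name` or `marker_name`, `chromosome`, `span_start`, `span_end`).
#' @param target Optional locus `c(start, end)` tested for overlap with
#'   the interval.
#' @return One-row tibble: `chromosome`, `start`, `end`, `size`,
#'   `flank_start_marker`, `flank_end_marker`, `n_support`,
#'   `contains_target`.
#' @export
make_interval <- function(run_markers, target = NULL) {
  stopifnot(nrow(run_markers) >= 1)
  nm <- if ("name" %in% names(run_markers)) run_markers$name
        else run_markers$marker_name
  i0 <- which.min(run_markers$span_start)
  i1 <- which.max(run_markers$span_start)
  start <- run_markers$span_start[i0]
  end <- run_markers$span_end[i1]
  if (!(start < end)) stop("degenerate interval: start >= end", call. = FALSE)
  tibble::tibble(
    chromosome = run_markers$chromosome[1],
    start = start, end = end, size = end - start,
    flank_start_marker = nm[i0], flank_end_marker = nm[i1],
    n_support = nrow(run_markers),
    contains_target = if (is.null(target)) NA
                      else target[1] <= end && target[2] >= start)
}

#' Map deletion intervals from per-marker calls
#'
#' Chains [find_runs()], [make_interval()] and [assign_subgenome()] over a
#' calls table. With `project_sites` (the default), a multi-site probe is
#' placed on every chromosome it hybridises to, at that chromosome's site
#' position — the convention of array marker tables, where the same SNP
#' index is listed under each homoeologous chromosome. A flagged probe
#' therefore supports a run wherever it binds: on the deleted chromosome
#' the run is anchored at the deleted sites themselves, while on the other
#' homoeologues it forms a diffuse shadow run. Shadow runs lack single-site
#' null support and come out `"unassigned"`, which is how the subgenome
#' validation separates the true location from its homoeologous shadows.
#'
#' @param calls Calls tibble from [call_deletions()].
#' @param markers Marker records (site positions and single-site subgenome
#'   evidence).
#' @param config A [mapper_config()].
#' @param project_sites Place each marker at its per-chromosome
#'   hybridisation-site positions (default); `FALSE` uses only the
#'   assembly span of each marker.
#' @return Intervals tibble, one row per run, with subgenome attribution
#'   and HET support counts; run membership in `attr(, "runs")`.
#' @export
map_intervals <- function(calls, markers, config = mapper_config(),
                          project_sites = TRUE) {
  placed <- if (project_sites) .place_calls(calls, markers) else calls
  runs <- find_runs(placed, config)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    mem <- placed[placed$chromosome == runs$chromosome[i] &
                    placed$marker_name %in% runs$marker_names[[i]], ]
    target <- config$target_loci[[runs$chromosome[i]]]
    iv <- make_interval(mem, target)
    sg <- assign_subgenome(calls[calls$marker_name %in% mem$marker_name, ],
                           markers)
    tibble::tibble(iv[, c("chromosome", "start", "end", "size",
                          "flank_start_marker", "flank_end_marker",
                          "n_support")],
                   n_discordant = length(runs$discordant[[i]]),
                   n_het_confirmed = sum(mem$het_confirmed, na.rm = TRUE),
                   subgenome = as.character(sg),
                   contains_target = iv$contains_target)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    out <- tibble::tibble(chromosome = character(), start = numeric(),
                          end = numeric(), size = numeric(),
                          flank_start_marker = character(),
                          flank_end_marker = character(),
                          n_support = integer(), n_discordant = integer(),
                          n_het_confirmed = integer(),
                          subgenome = character(), contains_target = logical())
  attr(out, "runs") <- runs
  out
}

# place each call on every chromosome its probe hybridises to, at the site
# position there (probe span width preserved)
.place_calls <- function(calls, markers) {
  m <- match(calls$marker_name, markers$name)
  if (anyNA(m))
    stop("calls contain markers absent from the marker table", call. = FALSE)
  k <- vapply(markers$sites[m], nrow, integer(1))
  flat <- do.call(rbind, markers$sites[m])
  idx <- rep.int(seq_len(nrow(calls)), k)
  width <- (markers$span_end - markers$span_start)[m][idx]
  placed <- calls[idx, ]
  placed$chromosome <- flat$subgenome
  placed$span_start <- flat$position
  placed$span_end <- flat$position + width
  placed
}

#' Compare mapped intervals with simulation ground truth
#'
#' For each true deletion, looks for a mapped interval on the matching
#' assembly chromosome that overlaps it, and reports boundary errors and
#' subgenome attribution. Because flanking markers lie inside the deleted
#' segment, a recovered interval is nested within the true deletion and
#' each boundary error is at most the distance from the true breakpoint to
#' the nearest informative marker.
#'
#' @param intervals Output of [map_intervals()].
#' @param truth Truth record from [simulate_experiment()] (`$truth`), or
#'   its `deletions` tibble.
#' @param span_slack Tolerance (bp) allowed on `nested`: interval
#'   coordinates carry the full probe span, and a probe anchored just
#'   inside a breakpoint can overhang it by up to its span width.
#' @return Tibble: one row per true deletion record, with `detected`,
#'   `boundary_error_start`, `boundary_error_end`, `subgenome_assigned`,
#'   `subgenome_correct`, `nested` (interval inside truth).
#' @export
recover_truth <- function(intervals, truth, span_slack = 0) {
  dels <- if (is.data.frame(truth)) truth else truth$deletions
  if (is.null(dels) || nrow(dels) == 0)
    return(tibble::tibble(sample_id = character(), subgenome = character(),
                          detected = logical(),
                          boundary_error_start = numeric(),
                          boundary_error_end = numeric(),
                          subgenome_assigned = character(),
                          subgenome_correct = logical(), nested = logical()))
  rows <- lapply(seq_len(nrow(dels)), function(i) {
    d <- dels[i, ]
    cand <- intervals[intervals$chromosome == d$subgenome &
                        intervals$start <= d$end & intervals$end >= d$start, ]
    if (nrow(cand) == 0)
      return(tibble::tibble(sample_id = d$sample_id, subgenome = d$subgenome,
                            detected = FALSE, boundary_error_start = NA_real_,
                            boundary_error_end = NA_real_,
                            subgenome_assigned = NA_character_,
                            subgenome_correct = NA, nested = NA))
    best <- cand[which.max(pmin(cand$end, d$end) - pmax(cand$start, d$start)), ]
    tibble::tibble(sample_id = d$sample_id, subgenome = d$subgenome,
                   detected = TRUE,
                   boundary_error_start = abs(best$start - d$start),
                   boundary_error_end = abs(best$end - d$end),
                   subgenome_assigned = best$subgenome,
                   subgenome_correct = identical(best$subgenome, d$subgenome),
                   nested = best$start >= d$start - span_slack &&
                     best$end <= d$end + span_slack)
  })
  dplyr::bind_rows(rows)
}
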