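#' Caller thresholds and options
#'
#' @param theta_threshold Minimum |NormTheta shift| flagging a putative
#'   deletion marker (unitless, default 0.1).
#' @param r_threshold Minimum |NormR shift| flagging a putative deletion
#'   marker (signal units, default 0.5). Flagging is the disjunction of the
#'   two axes; values exactly at a threshold are flagged.
#' @param null_floor NormR below which an observation is a null allele.
#' @param het_tolerance Maximum distance of the F1 theta from the
#'   parent/mutant midpoint for heterozygous confirmation. Exact halfway
#'   does not hold under the polar dosage model (the arctangent is not
#'   linear in dosage), so a small tolerance is required; 0.05 covers the
#'   model's largest midpoint offset with room for noise.
#' @param require_panel_concordance When a panel-average reference exists,
#'   require the shift criterion to hold against it as well.
#' @return A `caller_config` list.
#' @export
caller_config <- function(theta_threshold = 0.1, r_threshold = 0.5,
                          null_floor = 0.2, het_tolerance = 0.05,
                          require_panel_concordance = TRUE) {
  if (theta_threshold <= 0 || r_threshold <= 0 || null_floor <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  structure(list(theta_threshold = theta_threshold, r_threshold = r_threshold,
                 null_floor = null_floor, het_tolerance = het_tolerance,
                 require_panel_concordance = isTRUE(require_panel_concordance)),
            class = "caller_config")
}

#' Cluster shift between a reference and a sample
#'
#' Signed differences `reference - sample` on both cluster axes, the
#' convention under which a deletion (loss of B-channel or total signal)
#' gives positive `d_r`. An undefined theta on either side yields `NA`
#' `d_theta` while `d_r` is still computed.
#'
#' @param reference_obs,sample_obs Observation tibbles (`marker_name`,
#'   `norm_theta`, `norm_r`), row-aligned on the same markers.
#' @param reference Label recorded for the reference ("parent" or
#'   "panel_average").
#' @return Tibble `marker_name`, `reference`, `d_theta`, `d_r`.
#' @export
compute_shift <- function(reference_obs, sample_obs, reference = "parent") {
  if (nrow(reference_obs) != nrow(sample_obs) ||
      any(reference_obs$marker_name != sample_obs$marker_name))
    stop("reference and sample observations must be aligned on the same markers",
         call. = FALSE)
  tibble::tibble(marker_name = reference_obs$marker_name,
                 reference = reference,
                 d_theta = reference_obs$norm_theta - sample_obs$norm_theta,
                 d_r = reference_obs$norm_r - sample_obs$norm_r)
}

#' Average cluster position of a reference panel
#'
#' Arithmetic mean of the defined thetas and of all NormR values per
#' marker; the synthetic counterpart of an "average unrelated-mutant"
#' reference cluster. If no panel observation has a defined theta the mean
#' theta is `NA` (undefined) with the mean R still reported.
#'
#' @param obs Panel observations (>= 1 sample), long tibble.
#' @return One row per marker, `sample_id = "AV_HIB"`.
#' @export
panel_average <- function(obs) {
  if (nrow(obs) == 0) stop("no panel observations", call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(obs, .data$marker_name),
    norm_theta = if (all(is.na(.data$norm_theta))) NA_real_
                 else mean(.data$norm_theta, na.rm = TRUE),
    norm_r = mean(.data$norm_r), .groups = "drop")
  tibble::tibble(sample_id = "AV_HIB", out)
}

#' Flag a putative deletion marker from its cluster shifts
#'
#' A marker is flagged when `|d_theta| >= theta_threshold` OR
#' `|d_r| >= r_threshold` against the parent; with
#' `require_panel_concordance` and a panel shift present, the same
#' disjunction must also hold against the panel average. `NA` axis values
#' contribute `FALSE` to the disjunction.
#'
#' @param shift_parent Shift tibble vs the euploid parent.
#' @param shift_panel Optional shift tibble vs the panel average, aligned.
#' @param config A [caller_config()].
#' @return Logical vector, one element per marker.
#' @export
flag_marker <- function(shift_parent, shift_panel = NULL,
                        config = caller_config()) {
  hit <- function(s) {
    (!is.na(s$d_theta) & abs(s$d_theta) >= config$theta_threshold) |
      (!is.na(s$d_r) & abs(s$d_r) >= config$r_threshold)
  }
  f <- hit(shift_parent)
  if (config$require_panel_concordance && !is.null(shift_panel)) {
    if (nrow(shift_panel) != nrow(shift_parent))
      stop("panel shifts must be aligned with parent shifts", call. = FALSE)
    f <- f & hit(shift_panel)
  }
  f
}

#' Null (no-fluorescence) allele detection
#'
#' @param obs Observation tibble.
#' @param null_floor NormR floor below which fluorescence is absent.
#' @return Logical vector: `norm_r < null_floor`.
#' @export
detect_null <- function(obs, null_floor = 0.2) obs$norm_r < null_floor

#' Heterozygous confirmation from a backcross F1 cluster
#'
#' A deletion is confirmed heterozygous when the F1 theta lies strictly
#' between the parent and mutant thetas and within `het_tolerance` of
#' their midpoint.
#'
#' @param parent_theta,mutant_theta,f1_theta Theta values (vectorised).
#' @param het_tolerance Midpoint tolerance, see [caller_config()].
#' @return Logical vector; `NA` where any theta is undefined
#'   (indeterminate).
#' @export
confirm_het <- function(parent_theta, mutant_theta, f1_theta,
                        het_tolerance = 0.05) {
  lo <- pmin(parent_theta, mutant_theta)
  hi <- pmax(parent_theta, mutant_theta)
  mid <- (parent_theta + mutant_theta) / 2
  ok <- f1_theta > lo & f1_theta < hi & abs(f1_theta - mid) <= het_tolerance
  ok[is.na(parent_theta) | is.na(mutant_theta) | is.na(f1_theta)] <- NA
  ok
}

#' Remove parent-stock biotype markers from deletion evidence
#'
#' Markers at which the two parent seed stocks (the stock the mutants were
#' derived from and the stock used for backcrossing) differ by at least
#' `threshold` in theta reflect pre-existing stock heterogeneity, not
#' mutagen damage; they are unflagged and listed in a biotype report.
#' Markers where exactly one stock has a defined theta are also treated as
#' discordant.
#'
#' @param calls Calls tibble (from [call_deletions()] or with at least
#'   `marker_name` and `flagged`).
#' @param parent_obs_hib_stock,parent_obs_backcross_stock Observation
#'   tibbles for the two stocks, aligned on the same markers.
#' @param threshold Theta discordance threshold (default 0.1).
#' @return `calls` with biotype markers unflagged and a logical `biotype`
#'   column; the report is in `attr(, "biotype_report")`.
#' @export
exclude_biotype_markers <- function(calls, parent_obs_hib_stock,
                                    parent_obs_backcross_stock,
                                    threshold = 0.1) {
  a <- parent_obs_hib_stock
  b <- parent_obs_backcross_stock
  if (any(a$marker_name != b$marker_name))
    stop("parent stock observations must be aligned", call. = FALSE)
  delta <- abs(a$norm_theta - b$norm_theta)
  disc <- (!is.na(delta) & delta >= threshold) | xor(is.na(a$norm_theta),
                                                    is.na(b$norm_theta))
  bad <- a$marker_name[disc]
  calls$biotype <- calls$marker_name %in% bad
  calls$flagged <- calls$flagged & !calls$biotype
  attr(calls, "biotype_report") <- tibble::tibble(
    marker_name = bad,
    theta_hib_stock = a$norm_theta[disc],
    theta_backcross_stock = b$norm_theta[disc],
    d_theta = delta[disc])
  calls
}

#' Subgenome attribution from single-site null markers
#'
#' Multi-site probes shift wherever any homoeologous site is lost, so they
#' cannot place a deletion on a subgenome. Probes with a single
#' hybridisation site can: a null allele at a single-site marker places the
#' deletion on that site's subgenome. Nulls on different subgenomes are a
#' conflict and leave the region unassigned.
#'
#' @param calls Calls for the candidate region (with `status`).
#' @param markers Marker records covering those calls.
#' @return A single subgenome label, or `"unassigned"`; the per-marker
#'   evidence is in `attr(, "votes")`.
#' @export
assign_subgenome <- function(calls, markers) {
  m <- markers[match(calls$marker_name, markers$name), ]
  single <- n_sites(m) == 1L
  nulls <- !is.na(calls$status) & calls$status == "null" & single
  votes <- vapply(m$sites[nulls], function(s) s$subgenome[1], character(1))
  lab <- if (length(votes) == 0 || length(unique(votes)) > 1) "unassigned"
         else unique(votes)
  structure(lab, votes = tibble::tibble(
    marker_name = calls$marker_name[nulls], subgenome = votes))
}

#' Call putative deletion markers for one sample
#'
#' Runs the per-marker evidence chain for one mutant (or backcross F1)
#' against the euploid parent: cluster shifts versus parent and versus the
#' panel average, threshold flagging, null-allele detection, optional
#' heterozygous confirmation against an F1 sample, parent-stock biotype
#' exclusion, and single-site subgenome evidence. Markers whose parent
#' observation is itself null are uninformative and never flagged.
#'
#' @param intensities Long observation tibble
#'   (`sample_id`, `marker_name`, `norm_theta`, `norm_r`).
#' @param markers Marker records ([read_marker_map()] /
#'   [build_marker_panel()]).
#' @param parent,sample Sample ids of the euploid parent and the queried
#'   line.
#' @param f1 Optional backcross F1 sample id (for HET confirmation of
#'   `sample`'s flagged markers).
#' @param panel Optional character vector of panel sample ids, or a regex
#'   prefix via `panel_prefix`.
#' @param panel_prefix Optional prefix selecting panel sample ids.
#' @param parent_bc Optional sample id of the backcross parent stock, for
#'   biotype exclusion.
#' @param config A [caller_config()].
#' @return Calls tibble, one row per marker: position columns, `status`
#'   (`"poly"`, `"null"`, `"none"`), `flagged`, shifts vs parent and panel,
#'   `het_confirmed`, `subgenome`, `biotype`, `parent_null`. Attributes
#'   `biotype_report` and `config`.
#' @export
call_deletions <- function(intensities, markers, parent, sample, f1 = NULL,
                           panel = NULL, panel_prefix = NULL,
                           parent_bc = NULL, config = caller_config()) {
  get_obs <- function(id) {
    o <- intensities[intensities$sample_id == id, ]
    if (nrow(o) == 0)
      stop("sample '", id, "' not found in the intensity table", call. = FALSE)
    o[match(markers$name, o$marker_name), ]
  }
  obs_p <- get_obs(parent)
  obs_s <- get_obs(sample)

  sh_parent <- compute_shift(obs_p, obs_s, "parent")
  sh_panel <- NULL
  if (!is.null(panel_prefix))
    panel <- setdiff(grep(paste0("^", panel_prefix),
                          unique(intensities$sample_id), value = TRUE),
                     c(parent, sample, f1, parent_bc))
  if (!is.null(panel) && length(panel) > 0) {
    pav <- panel_average(intensities[intensities$sample_id %in% panel, ])
    pav <- pav[match(markers$name, pav$marker_name), ]
    sh_panel <- compute_shift(pav, obs_s, "panel_average")
  }

  parent_null <- detect_null(obs_p, config$null_floor)
  flagged <- flag_marker(sh_parent, sh_panel, config) & !parent_null
  is_null <- detect_null(obs_s, config$null_floor) & !parent_null

  status <- rep("none", nrow(markers))
  status[flagged] <- "poly"
  status[flagged & is_null] <- "null"

  single_site <- n_sites(markers) == 1L
  site_sub <- vapply(markers$sites, function(s) s$subgenome[1], character(1))

  het <- rep(NA, nrow(markers))
  if (!is.null(f1)) {
    obs_f1 <- get_obs(f1)
    het <- confirm_het(obs_p$norm_theta, obs_s$norm_theta, obs_f1$norm_theta,
                       config$het_tolerance)
    # HET confirmation is only meaningful for putative deletion markers, and
    # only for multi-site probes whose theta responds to dosage; a
    # single-site probe's deletion evidence is its R drop / null, and a null
    # observation's theta is residual noise
    het[!flagged | single_site | is_null |
          detect_null(obs_f1, config$null_floor)] <- NA
  }

  calls <- tibble::tibble(
    marker_name = markers$name, chromosome = markers$chromosome,
    span_start = markers$span_start, span_end = markers$span_end,
    status = status, flagged = flagged,
    d_theta_parent = sh_parent$d_theta, d_r_parent = sh_parent$d_r,
    d_theta_panel = if (is.null(sh_panel)) NA_real_ else sh_panel$d_theta,
    d_r_panel = if (is.null(sh_panel)) NA_real_ else sh_panel$d_r,
    het_confirmed = het,
    subgenome = ifelse(single_site & status == "null", site_sub, NA_character_),
    parent_null = parent_null, biotype = FALSE)

  if (!is.null(parent_bc)) {
    obs_bc <- get_obs(parent_bc)
    calls <- exclude_biotype_markers(calls, obs_p, obs_bc,
                                     config$theta_threshold)
    calls$status[calls$biotype] <- "none"
  }
  attr(calls, "config") <- config
  calls
}
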