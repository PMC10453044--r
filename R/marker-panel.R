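#' Build a synthetic marker panel
#'
#' Draws `n_markers` probes. Each probe has a primary hybridisation site on
#' its assembly chromosome (uniform position); a `multisite_fraction` of
#' probes additionally hybridise to homoeologous sites on one or two of the
#' other subgenomes, offset by at most `homoeo_jitter` bp from the primary
#' position. Each site carries an A or B allele and a per-copy signal gain.
#'
#' @param config A [sim_config()].
#' @return A tibble of marker records sorted by (chromosome, span_start):
#'   `snp_index`, `name`, `chromosome`, `span_start`, `span_end` and a
#'   `sites` list-column of per-site data frames
#'   (`subgenome`, `position`, `allele`, `gain`).
#' @export
build_marker_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .build_panel(config))
}

.build_panel <- function(cfg) {
  n <- cfg$n_markers
  sg <- cfg$subgenomes
  primary <- sample(sg, n, replace = TRUE)
  pos <- sample.int(max(cfg$chrom_length - 200L, 1L), n, replace = TRUE)
  n_sites <- rep(1L, n)
  multi <- runif(n) < cfg$multisite_fraction & length(sg) >= 2
  if (any(multi)) {
    kmax <- min(3L, length(sg))
    n_sites[multi] <- sample(2:kmax, sum(multi), replace = TRUE,
                             prob = cfg$site_count_probs[seq_len(kmax - 1L)])
  }

  # flat site table: primary site first, then homoeologous sites
  midx <- rep.int(seq_len(n), n_sites)
  extra <- n_sites - 1L
  others <- lapply(seq_len(n), function(i) {
    o <- setdiff(sg, primary[i])
    if (extra[i] == 0L) character(0)
    else if (extra[i] >= length(o)) sample(o)
    else sample(o, extra[i])
  })
  site_sub <- unlist(lapply(seq_len(n), function(i) c(primary[i], others[[i]])),
                     use.names = FALSE)
  is_primary <- unlist(lapply(n_sites, function(k) c(TRUE, rep(FALSE, k - 1L))),
                       use.names = FALSE)
  jit <- round(runif(length(midx), -cfg$homoeo_jitter, cfg$homoeo_jitter))
  site_pos <- ifelse(is_primary, pos[midx],
                     pmin(pmax(pos[midx] + jit, 1), cfg$chrom_length))
  allele <- sample(c("A", "B"), length(midx), replace = TRUE)
  flat <- data.frame(midx = midx, subgenome = site_sub, position = site_pos,
                     allele = allele, gain = cfg$gain,
                     stringsAsFactors = FALSE)

  mk <- tibble::tibble(chromosome = primary, span_start = pos,
                       span_end = pos + 100L,
                       sites = unname(split(flat[-1L], factor(midx, seq_len(n)))))
  ord <- order(mk$chromosome, mk$span_start)
  mk <- mk[ord, ]
  mk$snp_index <- seq_len(n)
  mk$name <- sprintf("SYN%05d", seq_len(n))
  mk[, c("snp_index", "name", "chromosome", "span_start", "span_end", "sites")]
}

#' Flatten a marker panel's hybridisation sites
#'
#' @param markers Marker tibble from [build_marker_panel()] or
#'   [read_marker_map()].
#' @return One row per hybridisation site, with the owning marker's `name`
#'   and `chromosome`.
#' @export
marker_sites <- function(markers) {
  k <- vapply(markers$sites, nrow, integer(1))
  flat <- do.call(rbind, markers$sites)
  tibble::tibble(name = rep.int(markers$name, k),
                 chromosome = rep.int(markers$chromosome, k),
                 subgenome = flat$subgenome, position = flat$position,
                 allele = flat$allele, gain = flat$gain)
}

#' Number of hybridisation sites per marker
#' @param markers Marker tibble.
#' @return Integer vector aligned with `markers`.
#' @export
n_sites <- function(markers) vapply(markers$sites, nrow, integer(1))
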