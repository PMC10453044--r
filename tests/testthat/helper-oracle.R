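# Independent closed-form oracle for the dosage signal model: plain loops,
# no code shared with the package's vectorised implementation.

oracle_theta_r <- function(sites, copies) {
  x <- 0
  y <- 0
  for (j in seq_len(nrow(sites))) {
    v <- sites$gain[j] * copies[j]
    if (sites$allele[j] == "A") x <- x + v else y <- y + v
  }
  if (x == 0 && y == 0) list(theta = NA_real_, r = 0)
  else list(theta = (2 / pi) * atan2(y, x), r = x + y)
}

oracle_copies <- function(sites, deletion, zygosity = "hom") {
  cp <- rep(2, nrow(sites))
  if (!is.null(deletion)) {
    ins <- sites$subgenome == deletion$subgenome &
      sites$position >= deletion$start & sites$position <= deletion$end
    cp[ins] <- if (zygosity == "hom") 0 else 1
  }
  cp
}

# brute-force prediction of the flagged-marker set for one hom deletion,
# noise-free euploid parent vs mutant
oracle_flags <- function(markers, deletion,
                         theta_threshold = 0.1, r_threshold = 0.5) {
  vapply(seq_len(nrow(markers)), function(i) {
    s <- markers$sites[[i]]
    eu <- oracle_theta_r(s, rep(2, nrow(s)))
    mu <- oracle_theta_r(s, oracle_copies(s, deletion))
    dth <- if (is.na(eu$theta) || is.na(mu$theta)) NA_real_
           else eu$theta - mu$theta
    dr <- eu$r - mu$r
    (!is.na(dth) && abs(dth) >= theta_threshold) || abs(dr) >= r_threshold
  }, logical(1))
}

# 3-site reference geometry used across the calling tests:
# A site on 6A, B sites on 6B and 6D, unit gains
ref_sites <- function() {
  data.frame(subgenome = c("6A", "6B", "6D"),
             position = c(1e6, 1.1e6, 0.9e6),
             allele = c("A", "B", "B"), gain = 1,
             stringsAsFactors = FALSE)
}

obs_row <- function(marker, theta, r, id = "s") {
  tibble::tibble(sample_id = id, marker_name = marker,
                 norm_theta = theta, norm_r = r)
}
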