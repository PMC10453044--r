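#' Two-channel allele-dosage signal model
#'
#' Computes the Infinium-style polar cluster coordinates of one probe for
#' one sample. Channel sums are linear in allele dosage:
#' \deqn{X = \sum_{A\text{-sites}} g_i d_i + \epsilon_X,\qquad
#'       Y = \sum_{B\text{-sites}} g_i d_i + \epsilon_Y,}
#' with per-channel Gaussian noise clamped at zero, and
#' \deqn{\theta = \frac{2}{\pi}\,\mathrm{atan2}(Y, X),\qquad R = X + Y.}
#' When both channels are zero (a null allele with no fluorescence),
#' `norm_theta` is `NA` and `norm_r` is 0.
#'
#' @param sites Data frame of hybridisation sites
#'   (`subgenome`, `position`, `allele`, `gain`).
#' @param dosage Copy number per site: a single value in 0:2 applied to all
#'   sites, a vector aligned with `sites`, or a data frame with
#'   `subgenome`, `position`, `copies` (sites not listed default to 2).
#' @param noise_sd Per-channel Gaussian noise SD.
#' @param seed Optional seed for the noise draw.
#' @return A one-row tibble with `norm_theta` (in \[0, 1\] or `NA`) and
#'   `norm_r` (>= 0).
#' @examples
#' s <- data.frame(subgenome = c("6A", "6B", "6D"),
#'                 position = c(1e6, 1.2e6, 0.9e6),
#'                 allele = c("A", "B", "B"), gain = 1)
#' infinium_signal(s, 2)                    # euploid: theta = 2/pi * atan(2)
#' infinium_signal(s, c(0, 2, 2))           # 6A site deleted: theta = 1
#' @export
infinium_signal <- function(sites, dosage = 2, noise_sd = 0, seed = NULL) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("at least one hybridisation site is required", call. = FALSE)
  cp <- .site_copies(sites, dosage)
  if (!all(cp %in% 0:2)) stop("dosage values must be in {0, 1, 2}", call. = FALSE)
  a <- sum(sites$gain * cp * (sites$allele == "A"))
  b <- sum(sites$gain * cp * (sites$allele == "B"))
  draw <- function() {
    out <- .theta_r(a, b, noise_sd)
    tibble::tibble(norm_theta = out$norm_theta, norm_r = out$norm_r)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.site_copies <- function(sites, dosage) {
  if (is.data.frame(dosage)) {
    key <- paste(sites$subgenome, sites$position)
    m <- match(key, paste(dosage$subgenome, dosage$position))
    cp <- dosage$copies[m]
    cp[is.na(m)] <- 2
    cp
  } else if (length(dosage) == 1L) {
    rep(dosage, nrow(sites))
  } else {
    if (length(dosage) != nrow(sites))
      stop("`dosage` must be length 1 or one value per site", call. = FALSE)
    dosage
  }
}

# vectorised polar transform of noise-free channel sums
.theta_r <- function(a, b, noise_sd = 0) {
  if (noise_sd > 0) {
    a <- pmax(a + rnorm(length(a), 0, noise_sd), 0)
    b <- pmax(b + rnorm(length(b), 0, noise_sd), 0)
  }
  r <- a + b
  theta <- ifelse(r == 0, NA_real_, (2 / pi) * atan2(b, a))
  list(norm_theta = theta, norm_r = r)
}
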