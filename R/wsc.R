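#' Read a WSC phenotype table
#'
#' @param path CSV with columns `line`, `treatment`, `daa` (days after
#'   anthesis; negative for pre-anthesis stages), `stem_wsc_pct_dw`,
#'   `grain_weight_g`, `replicate`.
#' @return Tibble with those columns.
#' @export
read_wsc_phenotype <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    line = readr::col_character(), treatment = readr::col_character(),
    daa = readr::col_double(), stem_wsc_pct_dw = readr::col_double(),
    grain_weight_g = readr::col_double(), replicate = readr::col_integer()))
}

#' One line-by-treatment WSC time course (replicate means)
#'
#' @param pheno Phenotype tibble ([read_wsc_phenotype()]).
#' @param line,treatment Selectors.
#' @return Tibble `daa`, `wsc`, `grain_weight`, `n` sorted by `daa`.
#' @export
wsc_series <- function(pheno, line, treatment) {
  p <- pheno[pheno$line == line & pheno$treatment == treatment, ]
  if (nrow(p) == 0)
    stop("no observations for line '", line, "', treatment '", treatment, "'",
         call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(p, daa = .data$daa),
                          wsc = mean(.data$stem_wsc_pct_dw),
                          grain_weight = mean(.data$grain_weight_g),
                          n = dplyr::n(), .groups = "drop")
  out[order(out$daa), ]
}

#' Time of peak stem WSC
#'
#' @param series Series tibble with `daa` and `wsc` (e.g. [wsc_series()]).
#' @return The DAA of maximum stem WSC; ties break to the earliest DAA.
#' @export
find_peak <- function(series) {
  if (is.null(series) || nrow(series) == 0)
    stop("empty WSC series", call. = FALSE)
  s <- series[order(series$daa), ]
  s$daa[which.max(s$wsc)]
}

#' WSC remobilisation over a fixed post-anthesis window
#'
#' `decline = WSC(t_start) - WSC(t_end)` in %dw and
#' `rate = decline / (t_end - t_start)` in %dw per day. The default window
#' (12 to 22 DAA) spans peak stem WSC to the permanent wilting point under
#' terminal water deficit. Both quantities are reported because the
#' 10-day decline and the daily rate are easy to conflate.
#'
#' @param series Series tibble with `daa` and `wsc`.
#' @param t_start,t_end Window endpoints (DAA); observations must exist at
#'   both.
#' @return One-row tibble: `t_start`, `t_end`, `wsc_start`, `wsc_end`,
#'   `decline`, `rate`.
#' @export
wsc_remobilisation <- function(series, t_start = 12, t_end = 22) {
  val <- function(t) {
    v <- series$wsc[series$daa == t]
    if (length(v) == 0)
      stop("no WSC observation at ", t, " DAA", call. = FALSE)
    mean(v)
  }
  w0 <- val(t_start); w1 <- val(t_end)
  tibble::tibble(t_start = t_start, t_end = t_end,
                 wsc_start = w0, wsc_end = w1,
                 decline = w0 - w1, rate = (w0 - w1) / (t_end - t_start))
}

#' Relative slowdown of remobilisation versus the parent line
#'
#' `(parent_decline - line_decline) / parent_decline * 100`, in percent; a
#' positive value means the line remobilises more slowly than the parent.
#'
#' @param line_decline,parent_decline Window declines (%dw), scalars or
#'   rows from [wsc_remobilisation()].
#' @return Percent slowdown; `NA` with a warning when the parent decline
#'   is not positive (undefined).
#' @export
relative_slowdown <- function(line_decline, parent_decline) {
  if (is.data.frame(line_decline)) line_decline <- line_decline$decline
  if (is.data.frame(parent_decline)) parent_decline <- parent_decline$decline
  if (parent_decline <= 0) {
    warning("parent decline is not positive; relative slowdown undefined")
    return(NA_real_)
  }
  (parent_decline - line_decline) / parent_decline * 100
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return One-row tibble `r`, `p`, `n`; `r` is `NA` with a warning when
#'   either vector has zero variance.
#' @export
wsc_correlate <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Remobilisation summary for every line under one treatment
#'
#' @param pheno Phenotype tibble.
#' @param parent Parent line name (slowdown reference).
#' @param treatment Treatment to summarise (default `"water_deficit"`).
#' @param window Remobilisation window, `c(t_start, t_end)` in DAA.
#' @return Tibble, one row per line: peak DAA, window endpoints and
#'   values, `decline`, `rate`, `slowdown_vs_parent_pct`.
#' @export
remobilisation_table <- function(pheno, parent, treatment = "water_deficit",
                                 window = c(12, 22)) {
  lines <- unique(pheno$line)
  if (!parent %in% lines)
    stop("parent line '", parent, "' not in the phenotype table", call. = FALSE)
  res <- lapply(lines, function(ln) {
    s <- wsc_series(pheno, ln, treatment)
    tibble::tibble(line = ln, peak_daa = find_peak(s),
                   wsc_remobilisation(s, window[1], window[2]))
  })
  res <- dplyr::bind_rows(res)
  pd <- res$decline[res$line == parent]
  res$slowdown_vs_parent_pct <- vapply(res$decline, relative_slowdown,
                                       numeric(1), parent_decline = pd)
  res
}
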