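#' Parse genomic positions with arbitrary digit-grouping separators
#'
#' Printed marker tables group digits irregularly ("4,10,83,389"); every
#' non-digit character is stripped before conversion.
#'
#' @param x Character (or numeric) vector of positions.
#' @return Numeric vector; empty or all-separator strings give `NA`.
#' @export
parse_position <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  d <- gsub("[^0-9]", "", as.character(x))
  ifelse(d == "", NA_real_, suppressWarnings(as.numeric(d)))
}

.parse_sites <- function(txt, line_no) {
  if (is.na(txt) || trimws(txt) == "")
    stop("marker map line ", line_no, ": empty sites field", call. = FALSE)
  parts <- strsplit(strsplit(trimws(txt), ";", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  rows <- lapply(parts, function(p) {
    if (length(p) < 3 || length(p) > 4)
      stop("marker map line ", line_no, ": malformed site '",
           paste(p, collapse = ":"), "'", call. = FALSE)
    pos <- parse_position(p[2])
    if (is.na(pos))
      stop("marker map line ", line_no, ": bad site position '", p[2], "'",
           call. = FALSE)
    if (!p[3] %in% c("A", "B"))
      stop("marker map line ", line_no, ": site allele must be A or B",
           call. = FALSE)
    data.frame(subgenome = p[1], position = pos, allele = p[3],
               gain = if (length(p) == 4) as.numeric(p[4]) else 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a marker map CSV
#'
#' Expected header: `snp_index,name,chromosome,span_start,span_end,sites`.
#' Positions may carry digit-grouping separators; hybridisation sites are
#' encoded `subgenome:position:allele[:gain]`, `;`-delimited
#' (e.g. `6A:32658889:A;6B:57296208:B;6D:30282758:B`).
#'
#' @param path CSV file.
#' @return Marker tibble in the [build_marker_panel()] layout.
#' @export
read_marker_map <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("snp_index", "name", "chromosome", "span_start", "span_end", "sites")
  if (!all(need %in% names(raw)))
    stop("marker map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(raw$name))
    stop("duplicate marker names: ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "),
         call. = FALSE)
  tibble::tibble(
    snp_index = parse_position(raw$snp_index),
    name = raw$name, chromosome = raw$chromosome,
    span_start = parse_position(raw$span_start),
    span_end = parse_position(raw$span_end),
    sites = lapply(seq_len(nrow(raw)),
                   function(i) .parse_sites(raw$sites[i], i + 1L)))
}

#' Write a marker map CSV
#'
#' Inverse of [read_marker_map()] (plain un-grouped positions).
#'
#' @param markers Marker tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(markers, path) {
  enc <- vapply(markers$sites, function(s) {
    paste(ifelse(s$gain == 1,
                 paste(s$subgenome, s$position, s$allele, sep = ":"),
                 paste(s$subgenome, s$position, s$allele, s$gain, sep = ":")),
          collapse = ";")
  }, character(1))
  out <- data.frame(snp_index = markers$snp_index, name = markers$name,
                    chromosome = markers$chromosome,
                    span_start = markers$span_start,
                    span_end = markers$span_end, sites = enc)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write intensity observation tables
#'
#' CSV dialect `sample_id,marker_name,norm_theta,norm_r`; an empty
#' `norm_theta` field encodes an undefined theta (null allele,
#' `norm_r = 0`).
#'
#' @param path CSV file.
#' @return Long observation tibble.
#' @export
read_intensities <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  # base strtod is correctly rounded at full double precision
  tibble::tibble(sample_id = raw$sample_id, marker_name = raw$marker_name,
                 norm_theta = as.numeric(raw$norm_theta),
                 norm_r = as.numeric(raw$norm_r))
}

#' @rdname read_intensities
#' @param obs Observation tibble.
#' @export
write_intensities <- function(obs, path) {
  # 17 significant digits: doubles survive a write/read cycle exactly, so a
  # second write is byte-identical to the first
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(sample_id = obs$sample_id, marker_name = obs$marker_name,
                    norm_theta = num(obs$norm_theta), norm_r = num(obs$norm_r))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write per-marker calls and the biotype report
#'
#' @param calls Calls tibble from [call_deletions()].
#' @param path Output CSV for the calls.
#' @param biotype_path Optional output CSV for the biotype report attached
#'   to `calls`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, biotype_path = NULL) {
  cols <- c("marker_name", "chromosome", "span_start", "span_end", "status",
            "flagged", "d_theta_parent", "d_r_parent", "d_theta_panel",
            "d_r_panel", "het_confirmed", "subgenome", "biotype")
  readr::write_csv(calls[, intersect(cols, names(calls))], path, na = "")
  if (!is.null(biotype_path)) {
    rep <- attr(calls, "biotype_report")
    if (is.null(rep)) rep <- tibble::tibble(marker_name = character())
    readr::write_csv(rep, biotype_path, na = "")
  }
  invisible(path)
}

#' Write mapped intervals as CSV and BED
#'
#' Interval coordinates are 1-based inclusive internally and in the CSV;
#' the BED export converts to 0-based half-open (`start - 1`, `end`),
#' which is lossless in both directions.
#'
#' @param intervals Intervals tibble ([map_intervals()]).
#' @param path Output CSV.
#' @param bed_path Optional BED output.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, bed_path = NULL) {
  readr::write_csv(intervals, path, na = "")
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = intervals$chromosome,
                      chromStart = intervals$start - 1,
                      chromEnd = intervals$end,
                      name = paste0("del_", intervals$chromosome, "_",
                                    intervals$subgenome))
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  invisible(path)
}

#' Read a BED file back into 1-based inclusive intervals
#'
#' @param path BED file (3+ columns, 0-based half-open).
#' @return Tibble `chromosome`, `start`, `end` (1-based inclusive).
#' @export
read_bed_intervals <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  tibble::tibble(chromosome = as.character(bed[[1]]),
                 start = bed[[2]] + 1, end = bed[[3]])
}

#' Serialise / load a simulation truth record
#'
#' @param truth Truth list from [simulate_experiment()].
#' @param path JSON file.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$deletions <- tibble::as_tibble(x$deletions)
  x$biotype_markers <- as.character(unlist(x$biotype_markers))
  x
}

#' Read an expression table (TSV)
#'
#' @param path TSV with columns `gene_id`, `sample`, `stage`, `tpm`.
#' @return Expression tibble.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), sample = readr::col_character(),
    stage = readr::col_character(), tpm = readr::col_double()))
}
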