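## Plain-text readers/writers. Curves and profiles are CSV with '#'-prefixed
## 'key: value' metadata lines before the header; numbers are written with 12
## significant digits so write-then-read round-trips are lossless at that
## precision. Everything is UTF-8, '.' decimal, Unix newlines, and writers
## are deterministic byte-for-byte.

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

write_lines_unix <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_meta_csv <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2)
    parse_error(sprintf("%s: no data rows after header", path))
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) parse_error(sprintf("%s: %s", path,
                                            conditionMessage(e))))
  list(meta = meta, data = df, n_meta = length(meta_idx))
}

#' Write a magnetization curve to CSV
#'
#' Columns `time_s, signal`, preceded by `#` metadata lines holding the
#' acquisition frequency (MHz) and the sequence (`cpmg` for decay curves,
#' `saturation_recovery` for recovery curves).
#'
#' @param curve A [decay_curve()] or [recovery_curve()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, c("decay_curve", "recovery_curve")))
  sequence <- if (inherits(curve, "decay_curve")) "cpmg"
              else "saturation_recovery"
  lines <- c(sprintf("# sequence: %s", sequence),
             sprintf("# frequency_mhz: %s", fmt_num(curve$frequency / 1e6)),
             "time_s,signal",
             paste(fmt_num(curve$times), fmt_num(curve$signal), sep = ","))
  write_lines_unix(lines, path)
}

#' Read a magnetization curve from CSV
#'
#' Inverse of [write_curve()]. The `sequence` metadata line decides whether
#' a [decay_curve()] or [recovery_curve()] is returned. Missing columns,
#' missing metadata or non-monotone time values raise a parse error naming
#' the offending file and line.
#'
#' @param path File path.
#' @return A [decay_curve()] or [recovery_curve()].
#' @export
read_curve <- function(path) {
  parsed <- read_meta_csv(path)
  df <- parsed$data
  if (!all(c("time_s", "signal") %in% names(df)))
    parse_error(sprintf("%s: need columns time_s, signal", path))
  seqn <- parsed$meta[["sequence"]]
  freq <- suppressWarnings(as.numeric(parsed$meta[["frequency_mhz"]])) * 1e6
  if (is.null(seqn) || !seqn %in% c("cpmg", "saturation_recovery"))
    parse_error(sprintf("%s: missing or unknown '# sequence:' metadata", path))
  if (!length(freq) || is.na(freq))
    parse_error(sprintf("%s: missing '# frequency_mhz:' metadata", path))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    parse_error(sprintf("%s: time not strictly increasing at data row %d",
                        path, bad[1] + 1))
  ctor <- if (seqn == "cpmg") decay_curve else recovery_curve
  tryCatch(ctor(df$time_s, df$signal, freq),
           relax_input_error = function(e)
             parse_error(sprintf("%s: %s", path, conditionMessage(e))))
}

#' Write a dispersion profile to CSV
#'
#' Columns `frequency_hz, r1_s` and, when uncertainties are present,
#' `r1_err_s`; the sample id is kept in a `#` metadata line.
#'
#' @param profile A [dispersion_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dispersion_profile"))
  has_err <- !is.null(profile$r1_uncertainties)
  header <- if (has_err) "frequency_hz,r1_s,r1_err_s" else "frequency_hz,r1_s"
  rows <- if (has_err)
    paste(fmt_num(profile$frequencies), fmt_num(profile$r1_values),
          fmt_num(profile$r1_uncertainties), sep = ",")
  else
    paste(fmt_num(profile$frequencies), fmt_num(profile$r1_values), sep = ",")
  write_lines_unix(c(sprintf("# sample_id: %s", profile$sample_id),
                     header, rows), path)
}

#' Read a dispersion profile from CSV
#'
#' Inverse of [write_profile()]; rows are sorted by frequency on read.
#' Non-positive frequencies or rates raise a parse error.
#'
#' @param path File path.
#' @return A [dispersion_profile()].
#' @export
read_profile <- function(path) {
  parsed <- read_meta_csv(path)
  df <- parsed$data
  if (!all(c("frequency_hz", "r1_s") %in% names(df)))
    parse_error(sprintf("%s: need columns frequency_hz, r1_s", path))
  ord <- order(df$frequency_hz)
  df <- df[ord, , drop = FALSE]
  id <- parsed$meta[["sample_id"]]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  err <- if ("r1_err_s" %in% names(df)) df$r1_err_s else NULL
  tryCatch(dispersion_profile(id, df$frequency_hz, df$r1_s, err),
           relax_input_error = function(e)
             parse_error(sprintf("%s: %s", path, conditionMessage(e))))
}

#' Load the packaged lung-tissue marker fixture
#'
#' The published per-sample relaxation markers for the 19 lung-tissue
#' samples (tumor and peri-tumoral reference, patients P1--P10): power-law
#' exponent alpha, dispersion drop xi, the two spin--spin rates with their
#' printed uncertainties, the amplitude ratio r, the printed rate ratio and
#' the printed R2,slow/R1 quotient. Values are stored exactly as printed;
#' uncertainties keep their original precision.
#'
#' @return Data frame with 19 rows and columns `sample_id`, `group`,
#'   `alpha`, `alpha_err`, `xi`, `r2_slow`, `r2_slow_err`, `r2_fast`,
#'   `r2_fast_err`, `amp_ratio`, `rate_ratio`, `r2slow_over_r1`.
#' @export
load_published_markers <- function() {
  path <- system.file("extdata", "lung_markers_published.csv",
                      package = "relaxometry", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df
}

#' Write a marker table as CSV and aligned plain text
#'
#' Applies the report rounding conventions (alpha to 2 decimals, xi and r
#' to integer percent, rates to 3 significant digits, ratios to 1 decimal)
#' and writes a CSV plus, optionally, a fixed-width text rendering. Output
#' bytes are deterministic.
#'
#' @param table A `marker_table` from [build_marker_table()].
#' @param path CSV output path.
#' @param text_path Optional aligned-text output path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(table, path, text_path = NULL) {
  rounded <- round_marker_table(table)
  num_cols <- setdiff(names(rounded), c("sample_id", "group", "incomplete"))
  cells <- rounded
  for (cl in num_cols) cells[[cl]] <- ifelse(is.na(rounded[[cl]]), "NA",
                                             as.character(rounded[[cl]]))
  if ("incomplete" %in% names(cells))
    cells$incomplete <- ifelse(cells$incomplete, "yes", "no")
  lines <- c(paste(names(cells), collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  if (nrow(cells) == 0) lines <- lines[1]
  write_lines_unix(lines, path)
  if (!is.null(text_path)) {
    mat <- rbind(names(cells), as.matrix(cells))
    for (j in seq_len(ncol(mat)))
      mat[, j] <- formatC(mat[, j], width = max(nchar(mat[, j])),
                          flag = "-")
    txt <- trimws(apply(mat, 1, paste, collapse = "  "), which = "right")
    write_lines_unix(txt, text_path)
  }
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys raise a config
#' error. The format is chosen by file extension (`.yaml`/`.yml` vs
#' `.json`).
#'
#' @param path Config file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- tryCatch(
    switch(ext,
           yaml = , yml = yaml::read_yaml(path),
           json = jsonlite::read_json(path, simplifyVector = TRUE),
           config_error(sprintf("unsupported config format: .%s", ext))),
    error = function(e) config_error(sprintf("%s: %s", path,
                                             conditionMessage(e))))
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    config_error(sprintf("unknown config keys: %s",
                         paste(unknown, collapse = ", ")))
  vals <- lapply(vals, unlist)
  do.call(sim_config, vals)
}

sample_file_stem <- function(sample_id) {
  gsub("[^A-Za-z0-9_-]", "", gsub("[[:space:]]+", "_", sample_id))
}

#' Write a cohort bundle to a directory
#'
#' Creates `profiles/` and `decays/` CSV files (one per sample), a JSON
#' `manifest.json` and a `ground_truth.csv`, all deterministic given the
#' cohort. Inverse of [read_cohort()].
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  for (sub in c("profiles", "decays"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$profiles))
    write_profile(cohort$profiles[[id]],
                  file.path(dir, "profiles",
                            paste0(sample_file_stem(id), ".csv")))
  for (id in names(cohort$decays))
    write_curve(cohort$decays[[id]],
                file.path(dir, "decays",
                          paste0(sample_file_stem(id), ".csv")))
  manifest <- cohort$manifest
  manifest$file_stem <- vapply(manifest$sample_id, sample_file_stem, "")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  gt <- cohort$ground_truth
  gt_lines <- c(paste(names(gt), collapse = ","),
                apply(gt, 1, function(row) paste(trimws(row), collapse = ",")))
  write_lines_unix(gt_lines, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `manifest`, `profiles` and `decays` (named by
#'   sample_id); `ground_truth` when present.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    parse_error(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (anyDuplicated(manifest$sample_id))
    parse_error("duplicate sample_ids in manifest")
  if (!all(manifest$group %in% c("tumor", "reference")))
    parse_error("manifest group must be tumor or reference")
  profiles <- list()
  decays <- list()
  for (i in seq_len(nrow(manifest))) {
    stem <- manifest$file_stem[i]
    id <- manifest$sample_id[i]
    ppath <- file.path(dir, "profiles", paste0(stem, ".csv"))
    dpath <- file.path(dir, "decays", paste0(stem, ".csv"))
    if (file.exists(ppath)) profiles[[id]] <- read_profile(ppath)
    if (file.exists(dpath)) decays[[id]] <- read_curve(dpath)
  }
  gtp <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gtp))
    utils::read.csv(gtp, stringsAsFactors = FALSE) else NULL
  list(manifest = manifest, profiles = profiles, decays = decays,
       ground_truth = gt)
}
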