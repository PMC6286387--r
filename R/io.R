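## Readers and writers for the plain-text exchange formats:
## ITC heat tables (CSV + YAML design sidecar), SAXS .dat profiles,
## BMRB-flavoured shift TSVs, and SEC standards CSVs.

#' Write an ITC thermogram to CSV with a YAML design sidecar
#'
#' Columns: `injection_index`, `injection_volume_ul`, `heat_ucal`,
#' `kcal_per_mol_injectant`.  The design block (`cell_volume_ml`,
#' `syringe_um`, `cell_um`, `temp_c`) goes to `<path>.design.yml`.
#'
#' @param tg a [thermogram()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  d <- tg$design
  df <- data.frame(injection_index = seq_along(tg$heats_ucal),
                   injection_volume_ul = d$injection_volumes * 1e6,
                   heat_ucal = tg$heats_ucal,
                   kcal_per_mol_injectant = tg$heats_norm)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(cell_volume_ml = d$cell_volume * 1e3,
                        syringe_um = d$syringe_conc * 1e6,
                        cell_um = d$cell_conc * 1e6,
                        temp_c = d$temperature_c),
                   design_sidecar(path))
  invisible(path)
}

design_sidecar <- function(path) paste0(path, ".design.yml")

#' Read an ITC thermogram written by [write_itc_csv()]
#'
#' @param path CSV path; the design sidecar `<path>.design.yml` must
#'   exist unless `design` is supplied.
#' @param design optional [titration_design()] overriding the sidecar.
#' @return A [thermogram()].
#' @export
read_itc_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path)
  need <- c("injection_index", "injection_volume_ul", "heat_ucal")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected ITC CSV columns %s", path,
                 paste(need, collapse = ", ")))
  if (is.null(design)) {
    side <- design_sidecar(path)
    if (!file.exists(side))
      stop(sprintf("no design sidecar %s; pass `design` explicitly", side))
    y <- yaml::read_yaml(side)
    design <- titration_design(
      cell_volume = y$cell_volume_ml * 1e-3,
      injection_volumes = df$injection_volume_ul * 1e-6,
      syringe_conc = y$syringe_um * 1e-6,
      cell_conc = y$cell_um * 1e-6,
      temperature_c = y$temp_c)
  }
  thermogram(design, df$heat_ucal)
}

#' Write a SAXS profile in 3-column .dat dialect
#'
#' Whitespace-separated `q I sigma` rows (sigma column present only
#' when carried), with `#` comment headers.
#'
#' @param profile a [saxs_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SAXS profile: q [1/A]  I [arb]  sigma [arb]", con)
  if (!is.null(profile$concentration))
    writeLines(sprintf("# concentration_mg_ml: %g", profile$concentration),
               con)
  m <- if (is.null(profile$sigma)) cbind(profile$q, profile$I)
       else cbind(profile$q, profile$I, profile$sigma)
  utils::write.table(format(m, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a 3-column SAXS .dat profile
#'
#' Accepts whitespace- or comma-separated `q I [sigma]` rows; `#` lines
#' are comments.  A `# concentration_mg_ml:` header is honoured.
#'
#' @param path input path.
#' @return A [saxs_profile()].
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  conc <- NULL
  cl <- grep("concentration_mg_ml", comments, value = TRUE)
  if (length(cl))
    conc <- as.numeric(sub(".*concentration_mg_ml:\\s*", "", cl[1]))
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(trimws(gsub(",", " ", data_lines[i])), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop(sprintf("%s: line %d: expected 2-3 numeric columns (q I [sigma])",
                   path, i))
    v
  })
  ncols <- min(vapply(rows, length, 1L))
  m <- do.call(rbind, lapply(rows, `[`, seq_len(ncols)))
  saxs_profile(m[, 1], m[, 2],
               sigma = if (ncols >= 3) m[, 3] else NULL,
               concentration = conc)
}

#' Write a Ca shift table as BMRB-flavoured TSV
#'
#' Columns `residue_number`, `residue_type`, `atom`, `shift_ppm`;
#' unobserved residues are omitted.
#'
#' @param tab a [shift_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shift_tsv <- function(tab, path) {
  stopifnot(inherits(tab, "shift_table"))
  df <- as.data.frame(tab)[tab$observed, ]
  out <- data.frame(residue_number = df$residue_number,
                    residue_type = df$residue_type,
                    atom = "CA",
                    shift_ppm = df$ca_shift)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a Ca shift TSV
#'
#' Missing rows are tolerated (unobserved residues); supply
#' `full_range` to reinstate them as unobserved entries.
#'
#' @param path input path.
#' @param full_range optional integer vector of all residue numbers the
#'   construct spans; residues absent from the file are added as
#'   unobserved.
#' @param residue_types named residue-type vector used for reinstated
#'   residues (default [slr1_like_sequence()] over `full_range`).
#' @return A [shift_table()].
#' @export
read_shift_tsv <- function(path, full_range = NULL, residue_types = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_number", "residue_type", "atom", "shift_ppm")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected shift TSV columns %s", path,
                 paste(need, collapse = ", ")))
  df <- df[df$atom == "CA", ]
  if (!is.null(full_range)) {
    absent <- setdiff(full_range, df$residue_number)
    if (length(absent)) {
      if (is.null(residue_types))
        residue_types <- slr1_like_sequence(min(full_range), max(full_range))
      df <- rbind(df, data.frame(residue_number = absent,
                                 residue_type = unname(
                                   residue_types[as.character(absent)]),
                                 atom = "CA", shift_ppm = NA_real_))
    }
  }
  shift_table(df$residue_number, df$residue_type, df$shift_ppm)
}

#' Write SEC standards/samples CSV
#'
#' @param df data.frame with `name`, `elution_volume_ml` and optional
#'   `mw_kda`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gf_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read SEC standards/samples CSV
#'
#' @param path input path.
#' @return Data.frame with `name`, `elution_volume_ml`, and `mw_kda`
#'   when present.
#' @export
read_gf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "elution_volume_ml") %in% names(df)))
    stop(sprintf("%s: expected SEC CSV columns name, elution_volume_ml",
                 path))
  df
}
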