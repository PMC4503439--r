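# CSV dialects. Units are fixed by column name (time_min, conc_ug_ml,
# dose_mg_kg, ...); conversion happens at the boundary, never inside the
# analysis functions. Censored concentrations are written as "<LLOQ".

CONC_CSV_COLUMNS <- c("subject_id", "route", "dose_mg_kg", "matrix",
                      "time_min", "conc_ug_ml", "lloq_ug_ml")
PEAKLIST_CSV_COLUMNS <- c("peak_id", "precursor_mz", "rt_min", "fragments",
                          "sources")

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_adme(sprintf("%s lacks column(s): %s", what,
                       paste(missing, collapse = ", ")),
               "admekit_missing_column")
  }
}

#' Read concentration-time profiles from CSV
#'
#' Reads the package's concentration CSV dialect (one row per sample;
#' columns `subject_id`, `route`, `dose_mg_kg`, `matrix`, `time_min`,
#' `conc_ug_ml`, `lloq_ug_ml`; censored samples encoded as `"<LLOQ"`)
#' into a list of [conc_profile()] objects. Validation failures raise
#' distinct named errors (missing column, non-monotone times, negative
#' concentration).
#'
#' @param path CSV file path.
#' @return List of [conc_profile()] objects, one per
#'   subject-matrix combination.
#' @export
read_conc_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, CONC_CSV_COLUMNS, "concentration CSV")
  key <- paste(df$subject_id, df$matrix, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    censored <- trimws(as.character(d$conc_ug_ml)) == "<LLOQ"
    conc <- suppressWarnings(as.numeric(d$conc_ug_ml))
    conc[censored] <- NA_real_
    if (any(is.na(conc) & !censored)) {
      abort_adme("unparseable concentration value", "admekit_bad_conc")
    }
    if (any(conc < 0, na.rm = TRUE)) {
      abort_adme("negative concentration in CSV", "admekit_negative_conc")
    }
    if (is.unsorted(d$time_min, strictly = TRUE)) {
      abort_adme("sampling times not strictly increasing",
                 "admekit_nonmonotone_times")
    }
    conc_profile(subject_id = d$subject_id[1], times = d$time_min,
                 conc = conc, lloq = d$lloq_ug_ml[1],
                 matrix = d$matrix[1], route = d$route[1],
                 dose = d$dose_mg_kg[1], censored = censored)
  }) |> unname()
}

#' Write concentration-time profiles to CSV
#'
#' Inverse of [read_conc_csv()]: the round trip is the identity on the
#' canonical form (censored samples hold `NA` concentration and the
#' censored flag).
#'
#' @param profiles list of [conc_profile()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    conc <- ifelse(p$censored, "<LLOQ", format(p$conc, digits = 15))
    data.frame(subject_id = p$subject_id, route = p$route,
               dose_mg_kg = p$dose, matrix = p$matrix,
               time_min = p$times, conc_ug_ml = conc,
               lloq_ug_ml = p$lloq)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list from CSV
#'
#' Reads the peak-list CSV dialect: `peak_id`, `precursor_mz`, `rt_min`,
#' `fragments` (semicolon-separated m/z values) and `sources`
#' (semicolon-separated matrix names).
#'
#' @param path CSV file path.
#' @return Peak-list tibble with list-columns `fragments` and `sources`.
#' @export
read_peaklist_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, PEAKLIST_CSV_COLUMNS, "peak-list CSV")
  if (anyDuplicated(df$peak_id)) {
    abort_adme("duplicate peak_ids in peak-list CSV",
               "admekit_duplicate_peak")
  }
  if (any(!is.finite(df$precursor_mz)) || any(df$precursor_mz <= 0)) {
    abort_adme("precursor m/z must be positive", "admekit_bad_mz")
  }
  split_num <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric())
    as.numeric(strsplit(trimws(s), ";")[[1]])
  }
  split_chr <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    trimws(strsplit(trimws(s), ";")[[1]])
  }
  tibble::tibble(
    peak_id = df$peak_id,
    precursor_mz = df$precursor_mz,
    rt_min = df$rt_min,
    fragments = lapply(df$fragments, split_num),
    sources = lapply(df$sources, split_chr)
  )
}

#' Write a peak list to CSV
#'
#' @param peaks peak-list tibble (list-columns `fragments`, `sources`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(peaks, path) {
  df <- data.frame(
    peak_id = peaks$peak_id,
    precursor_mz = peaks$precursor_mz,
    rt_min = peaks$rt_min,
    fragments = vapply(peaks$fragments,
                       function(f) paste(format(f, digits = 15,
                                                trim = TRUE),
                                         collapse = ";"),
                       character(1)),
    sources = vapply(peaks$sources, paste, character(1), collapse = ";")
  )
  df$fragments[lengths(peaks$fragments) == 0] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis result table to CSV
#'
#' Thin tidy-CSV writer for result tables (NCA tables, annotation tables,
#' linearity evidence); list-columns are flattened with semicolons.
#'
#' @param results a data frame or tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], paste, character(1), collapse = ";")
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation provenance sidecar
#'
#' Records a simulation spec (and its seed) as JSON next to the data it
#' generated, so any simulated CSV can be regenerated exactly.
#'
#' @param spec a [pk_population_spec()] or [peaklist_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(spec, path) {
  jsonlite::write_json(c(list(class = class(spec)[1]), unclass(spec)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

CONFIG_DEFAULTS <- list(
  doses_iv = c(5, 10, 20),
  doses_oral = c(10, 50, 100),
  schedule_iv = c(0, 1, 5, 15, 30, 60, 90, 120, 180, 240, 300, 360),
  schedule_oral = c(0, 5, 15, 30, 60, 90, 120, 180, 240, 300, 360),
  alpha = 0.05,
  lloq_ug_ml = 0.001,
  auc_method = "linear_up_log_down",
  lambda_z_min_points = 3,
  mass_tolerance_da = 0.5,
  parent_mz = 411.21,
  parent_rt_min = 27.6,
  dilution_factor = 5,
  gfr_ml_min_kg = 14.0,
  output_dir = ".",
  seed = 1L
)

#' Pipeline configuration
#'
#' Returns the default pipeline configuration, or reads one from a YAML
#' file and validates it: unknown keys are rejected with a named error,
#' numeric fields are type-checked, and missing keys fall back to the
#' defaults.
#'
#' @param path optional YAML file path; `NULL` returns the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
#' @examples
#' read_config()
read_config <- function(path = NULL) {
  cfg <- CONFIG_DEFAULTS
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
    if (length(unknown)) {
      abort_adme(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 "admekit_unknown_key")
    }
    cfg[names(user)] <- user
  }
  numeric_keys <- setdiff(names(CONFIG_DEFAULTS),
                          c("auc_method", "output_dir"))
  for (k in numeric_keys) {
    if (!is.numeric(cfg[[k]]) || any(!is.finite(cfg[[k]]))) {
      abort_adme(sprintf("config key `%s` must be numeric", k),
                 "admekit_bad_config")
    }
  }
  if (!cfg$auc_method %in% c("linear_up_log_down", "linear")) {
    abort_adme("config `auc_method` must be linear_up_log_down or linear",
               "admekit_bad_config")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort_adme("config `alpha` must lie in (0, 1)", "admekit_bad_config")
  }
  structure(cfg, class = "pipeline_config")
}
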