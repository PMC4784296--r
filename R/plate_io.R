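#' Plate-level data container
#'
#' A `plate_run` holds the per-cycle fluorescence of every well of one qPCR
#' run (arbitrary instrument units, one reading at the end of each cycle)
#' plus, once attached, the plate map describing each well's role.
#'
#' @param cycles integer vector of cycle numbers, 1-based, consecutive.
#' @param fluor numeric matrix, `length(cycles)` rows x one column per well;
#'   column names are well ids.
#' @param meta optional plate-map `data.frame` (see [read_plate_map()]).
#' @param run_id text identifier for the run.
#' @return An object of class `plate_run`.
#' @export
new_plate_run <- function(cycles, fluor, meta = NULL, run_id = "") {
  cycles <- as.integer(cycles)
  if (length(cycles) < 1L || cycles[1] != 1L || any(diff(cycles) != 1L))
    qc_stop("cycle numbers must be 1-based and consecutive", "bad_cycles")
  if (nrow(fluor) != length(cycles))
    qc_stop("fluorescence series length must equal cycle count", "ragged_plate")
  rownames(fluor) <- NULL
  structure(list(cycles = cycles, fluor = fluor, meta = meta, run_id = run_id),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf("<plate_run '%s': %d wells x %d cycles%s>\n",
              x$run_id, ncol(x$fluor), length(x$cycles),
              if (is.null(x$meta)) ", no plate map" else ", plate map attached"))
  invisible(x)
}

#' Well ids of a plate run
#' @param run a [new_plate_run()] object.
#' @return character vector of well ids.
#' @export
wells <- function(run) colnames(run$fluor)

#' Read a per-cycle fluorescence table
#'
#' Two CSV dialects are supported.  `wide`: first column `cycle`, one further
#' column per well.  `long`: columns `well`, `cycle`, `fluorescence`.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param run_id run identifier; defaults to the file name without extension.
#' @return A `plate_run` with metadata unfilled.
#' @export
read_fluorescence_table <- function(path, dialect = c("wide", "long"),
                                    run_id = NULL) {
  dialect <- match.arg(dialect)
  run_id <- run_id %||% tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2L || tolower(names(df)[1]) != "cycle")
      qc_stop("wide dialect requires a first column named 'cycle'", "bad_format")
    num <- vapply(df, is.numeric, logical(1))
    if (!all(num))
      qc_stop(sprintf("non-numeric fluorescence values in column(s): %s",
                      paste(names(df)[!num], collapse = ", ")), "bad_format")
    df <- df[order(df[[1]]), , drop = FALSE]
    if (anyDuplicated(df[[1]]))
      qc_stop("duplicate cycle numbers in fluorescence table", "duplicate_cycle")
    fluor <- as.matrix(df[, -1, drop = FALSE])
    bad <- colnames(fluor)[colSums(is.na(fluor)) > 0]
    if (length(bad))
      qc_stop(sprintf("ragged plate: missing cycles for well(s) %s",
                      paste(bad, collapse = ", ")), "ragged_plate")
    return(new_plate_run(df[[1]], fluor, run_id = run_id))
  }
  ## long dialect
  need <- c("well", "cycle", "fluorescence")
  if (!all(need %in% tolower(names(df))))
    qc_stop("long dialect requires columns well, cycle, fluorescence", "bad_format")
  names(df) <- tolower(names(df))
  if (!is.numeric(df$fluorescence))
    qc_stop("non-numeric fluorescence values", "bad_format")
  if (anyDuplicated(df[, c("well", "cycle")]))
    qc_stop("duplicate (well, cycle) pairs in fluorescence table", "duplicate_cycle")
  cycles <- sort(unique(as.integer(df$cycle)))
  well_ids <- unique(df$well)
  fluor <- matrix(NA_real_, nrow = length(cycles), ncol = length(well_ids),
                  dimnames = list(NULL, well_ids))
  fluor[cbind(match(df$cycle, cycles), match(df$well, well_ids))] <- df$fluorescence
  bad <- well_ids[colSums(is.na(fluor)) > 0]
  if (length(bad))
    qc_stop(sprintf("ragged plate: missing cycles for well(s) %s",
                    paste(bad, collapse = ", ")), "ragged_plate")
  new_plate_run(cycles, fluor, run_id = run_id)
}

.plate_map_cols <- c("well", "role", "target", "sample_group", "replicate",
                     "calibrator_ng", "detection")

#' Read a plate map
#'
#' CSV with header `well,role,target,sample_group,replicate,calibrator_ng,detection`.
#' `role` is one of `sample`, `calibrator`, `ntc`; `calibrator_ng` must be a
#' non-negative amount in ng for calibrator wells (0 marks background wells)
#' and empty otherwise; `detection` is `dye` or `probe`.  Unknown extra
#' columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A `data.frame` with one row per well.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(.plate_map_cols, names(df))
  if (length(missing_cols))
    qc_stop(sprintf("plate map lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")), "bad_format")
  extra <- setdiff(names(df), .plate_map_cols)
  if (length(extra)) {
    qc_warn(sprintf("ignoring unknown plate-map column(s): %s",
                    paste(extra, collapse = ", ")), "unknown_columns")
    df <- df[, .plate_map_cols]
  }
  df$role <- tolower(df$role)
  bad_role <- setdiff(unique(df$role), c("sample", "calibrator", "ntc"))
  if (length(bad_role))
    qc_stop(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")),
            "bad_role")
  df$detection <- tolower(df$detection)
  bad_det <- setdiff(unique(df$detection), c("dye", "probe"))
  if (length(bad_det))
    qc_stop(sprintf("unknown detection(s): %s", paste(bad_det, collapse = ", ")),
            "bad_detection")
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    qc_stop("replicate must be a positive integer for every well", "bad_replicate")
  ng_raw <- df$calibrator_ng
  df$calibrator_ng <- suppressWarnings(as.numeric(ng_raw))
  is_cal <- df$role == "calibrator"
  if (any(is_cal & (is.na(df$calibrator_ng) | df$calibrator_ng < 0)))
    qc_stop(sprintf("calibrator well(s) without a valid calibrator_ng: %s",
                    paste(df$well[is_cal & is.na(df$calibrator_ng)], collapse = ", ")),
            "missing_calibrator_ng")
  if (any(!is_cal & nzchar(trimws(ng_raw))))
    qc_stop(sprintf("calibrator_ng set on non-calibrator well(s): %s",
                    paste(df$well[!is_cal & nzchar(trimws(ng_raw))], collapse = ", ")),
            "unexpected_calibrator_ng")
  if (anyDuplicated(df$well))
    qc_stop("duplicate well ids in plate map", "duplicate_well")
  df
}

#' Attach a plate map to a plate run
#'
#' Every well of the run must have exactly one matching plate-map row; map
#' rows for wells absent from the fluorescence table are dropped with a
#' warning.
#'
#' @param run a `plate_run`.
#' @param meta plate map as returned by [read_plate_map()].
#' @return The annotated `plate_run`.
#' @export
attach_metadata <- function(run, meta) {
  ids <- wells(run)
  orphans <- setdiff(ids, meta$well)
  if (length(orphans))
    qc_stop(sprintf("well(s) with no plate-map entry: %s",
                    paste(orphans, collapse = ", ")), "orphan_wells")
  extra <- setdiff(meta$well, ids)
  if (length(extra))
    qc_warn(sprintf("plate-map well(s) absent from fluorescence table: %s",
                    paste(extra, collapse = ", ")), "extra_meta")
  run$meta <- meta[match(ids, meta$well), , drop = FALSE]
  rownames(run$meta) <- NULL
  run
}

.report_cols <- c("well", "target", "group", "E", "takeoff", "sdm",
                  "window_start", "window_end", "mean_pmz", "sd_pmz", "sem_pmz",
                  "mean_copies", "sd_copies", "sem_copies", "flags")

#' Write a quantification report
#'
#' One row per well with the estimated efficiency, the exponential-window
#' landmarks, and the mean / SD / SEM of the back-calculated starting amount
#' in pmols and in copies per reaction.  Numbers are written with full
#' precision (>= 6 significant digits round-trip).
#'
#' @param results a list of [quantify_well()] results or a report
#'   `data.frame` (see [quant_table()]).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_quant_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (is.data.frame(results)) results else quant_table(results)
  if (nrow(df) == 0L)
    df <- df[, intersect(.report_cols, names(df)), drop = FALSE]
  miss <- setdiff(.report_cols, names(df))
  for (m in miss) df[[m]] <- if (m == "flags") character(0) else numeric(0)
  df <- df[, .report_cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a quantification report
#' @param path report path written by [write_quant_report()].
#' @param format `"csv"` or `"json"`.
#' @return report `data.frame`.
#' @export
read_quant_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
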