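#' Normalize raw sample collection times to the unit interval
#'
#' Sample collection times are mapped affinely onto `[0, 1]` so that the
#' first sample sits at 0 and the last at 1. Gaussian-process kernels are
#' evaluated on this normalized axis, which makes the time-scale parameter
#' comparable across studies measured in days, months or years.
#'
#' @param times_raw Numeric vector of strictly increasing collection times,
#'   in any unit.
#' @return Numeric vector of the same length in `[0, 1]`. A single time maps
#'   to 0.
#' @examples
#' normalize_times(c(10, 20, 40))
#' @export
normalize_times <- function(times_raw) {
  if (!is.numeric(times_raw) || length(times_raw) < 1L) {
    abort("`times_raw` must be a non-empty numeric vector.")
  }
  if (anyNA(times_raw)) abort("`times_raw` contains missing values.")
  if (length(times_raw) == 1L) return(0)
  if (any(diff(times_raw) <= 0)) {
    abort("Sample times must be strictly increasing (no duplicates).")
  }
  (times_raw - times_raw[1L]) / (times_raw[length(times_raw)] - times_raw[1L])
}

mutation_tbl_columns <- c(
  "mutation_id", "sample_id", "alt_reads", "total_reads",
  "total_cn", "multiplicity", "purity", "time_raw", "time"
)

new_mutation_tbl <- function(x, samples) {
  structure(x, samples = samples,
            class = c("mutation_tbl", class(tibble::tibble())))
}

#' Validate a long-format longitudinal mutation table
#'
#' Checks and canonicalizes a data frame with one row per (mutation, sample)
#' pair. Every mutation must be observed in every sample (a complete N x M
#' grid); purity and collection time must be constant within a sample.
#' Rows are ordered by normalized time, then mutation.
#'
#' @param df A data frame with columns `mutation_id`, `sample_id`,
#'   `alt_reads`, `total_reads`, `purity`, `time_raw`, and optionally
#'   `total_cn` (defaults to 2, diploid with no event) and `multiplicity`
#'   (defaults to `NA`, i.e. to be estimated from the data; see
#'   [resolve_multiplicity()]).
#' @return A `mutation_tbl`: a tibble with the columns above plus a
#'   normalized `time` column, carrying a per-sample metadata table in its
#'   `samples` attribute (see [sample_info()]).
#' @seealso [read_mutation_table()] for the on-disk format.
#' @export
as_mutation_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("mutation_id", "sample_id", "alt_reads", "total_reads",
                "purity", "time_raw")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"total_cn" %in% names(df)) df$total_cn <- 2L
  if (!"multiplicity" %in% names(df)) df$multiplicity <- NA_integer_
  df$total_cn[is.na(df$total_cn)] <- 2L

  for (col in c("alt_reads", "total_reads", "total_cn")) {
    x <- df[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x != round(x))) {
      abort(paste0("Column `", col, "` must contain whole numbers."))
    }
    df[[col]] <- as.integer(round(x))
  }
  mult <- df$multiplicity
  if (any(!is.na(mult) & (mult != round(mult) | mult < 1))) {
    abort("Column `multiplicity` must contain positive whole numbers (or NA).")
  }
  df$multiplicity <- as.integer(round(df$multiplicity))

  if (any(df$alt_reads < 0)) abort("`alt_reads` must be non-negative.")
  if (any(df$total_reads < 1)) abort("`total_reads` must be positive.")
  if (any(df$alt_reads > df$total_reads)) {
    bad <- df[df$alt_reads > df$total_reads, ]
    abort(paste0("`alt_reads` exceeds `total_reads` for: ",
                 paste(bad$mutation_id, bad$sample_id, sep = "@",
                       collapse = ", ")))
  }
  if (any(df$total_cn < 1)) abort("`total_cn` must be >= 1.")
  ok_mult <- is.na(df$multiplicity) | df$multiplicity <= df$total_cn
  if (!all(ok_mult)) {
    abort("`multiplicity` must not exceed `total_cn`.")
  }
  if (any(df$purity <= 0 | df$purity > 1)) {
    abort("`purity` must lie in (0, 1].")
  }

  # per-sample metadata must be constant within sample_id
  meta <- df |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_purity = dplyr::n_distinct(.data$purity),
      n_time = dplyr::n_distinct(.data$time_raw),
      purity = .data$purity[1L],
      time_raw = .data$time_raw[1L],
      .groups = "drop"
    )
  if (any(meta$n_purity > 1)) {
    abort(paste0("Purity is not constant within sample(s): ",
                 paste(meta$sample_id[meta$n_purity > 1], collapse = ", ")))
  }
  if (any(meta$n_time > 1)) {
    abort(paste0("Time is not constant within sample(s): ",
                 paste(meta$sample_id[meta$n_time > 1], collapse = ", ")))
  }
  meta <- meta |> dplyr::arrange(.data$time_raw)
  if (anyDuplicated(meta$time_raw)) {
    abort("Two samples share the same collection time; times must be unique.")
  }
  meta$time <- normalize_times(meta$time_raw)
  samples <- meta |>
    dplyr::select("sample_id", "time_raw", "time", "purity")

  # complete grid check
  grid <- tidyr::expand_grid(
    mutation_id = unique(df$mutation_id),
    sample_id = samples$sample_id
  )
  present <- paste(df$mutation_id, df$sample_id, sep = "\r")
  if (anyDuplicated(present)) {
    abort("Duplicate (mutation, sample) rows found.")
  }
  missing_cells <- grid[!paste(grid$mutation_id, grid$sample_id, sep = "\r")
                        %in% present, ]
  if (nrow(missing_cells) > 0) {
    abort(paste0(
      "Ragged grid: every mutation must appear in every sample. Missing: ",
      paste(missing_cells$mutation_id, missing_cells$sample_id,
            sep = "@", collapse = ", ")))
  }

  df$time <- samples$time[match(df$sample_id, samples$sample_id)]
  df <- df |>
    dplyr::select(dplyr::all_of(mutation_tbl_columns)) |>
    dplyr::arrange(.data$time, .data$mutation_id)
  new_mutation_tbl(df, samples)
}

#' Per-sample metadata of a mutation table
#'
#' @param tbl A `mutation_tbl` (see [as_mutation_table()]).
#' @return A tibble with one row per sample, ordered by collection time:
#'   `sample_id`, `time_raw`, normalized `time`, `purity`.
#' @export
sample_info <- function(tbl) {
  s <- attr(tbl, "samples")
  if (is.null(s)) s <- sample_info(as_mutation_table(tbl))
  s
}

#' Read a longitudinal mutation table from TSV or CSV
#'
#' The expected header columns are `mutationID`, `sampleID`, `altCounts`,
#' `totalCounts` (or `refCounts`, in which case totals are `alt + ref`),
#' `purity`, `time`, and optionally `cnTotal` (local total copy number,
#' default 2) and `cnMultiplicity` (variant multiplicity, estimated from the
#' data when absent).
#'
#' @param path Path to the delimited file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated `mutation_tbl`; see [as_mutation_table()].
#' @export
read_mutation_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  required <- c("mutationID", "sampleID", "altCounts", "purity", "time")
  missing_cols <- setdiff(required, names(raw))
  if (!any(c("totalCounts", "refCounts") %in% names(raw))) {
    missing_cols <- c(missing_cols, "totalCounts (or refCounts)")
  }
  if (length(missing_cols) > 0) {
    abort(paste0("Input file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  total <- if ("totalCounts" %in% names(raw)) {
    raw$totalCounts
  } else {
    raw$altCounts + raw$refCounts
  }
  df <- tibble::tibble(
    mutation_id = as.character(raw$mutationID),
    sample_id = as.character(raw$sampleID),
    alt_reads = raw$altCounts,
    total_reads = total,
    purity = raw$purity,
    time_raw = raw$time
  )
  if ("cnTotal" %in% names(raw)) df$total_cn <- raw$cnTotal
  if ("cnMultiplicity" %in% names(raw)) df$multiplicity <- raw$cnMultiplicity
  as_mutation_table(df)
}

#' Write a mutation table in the interchange TSV/CSV format
#'
#' Inverse of [read_mutation_table()]: emits columns `mutationID`,
#' `sampleID`, `altCounts`, `totalCounts`, `purity`, `time` (raw units),
#' `cnTotal` and, when any multiplicity is set, `cnMultiplicity`.
#'
#' @param tbl A `mutation_tbl`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(tbl, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- tibble::tibble(
    mutationID = tbl$mutation_id,
    sampleID = tbl$sample_id,
    altCounts = tbl$alt_reads,
    totalCounts = tbl$total_reads,
    purity = tbl$purity,
    time = tbl$time_raw,
    cnTotal = tbl$total_cn
  )
  if (any(!is.na(tbl$multiplicity))) out$cnMultiplicity <- tbl$multiplicity
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(out, path, progress = FALSE)
  invisible(path)
}

# Internal: reshape a mutation_tbl into N x M matrices used by the fitters.
# Columns are samples in time order; rows are mutations in id order.
table_arrays <- function(tbl) {
  samples <- sample_info(tbl)
  muts <- sort(unique(tbl$mutation_id))
  n <- length(muts)
  m <- nrow(samples)
  shape <- function(col) {
    mat <- matrix(NA_real_, n, m, dimnames = list(muts, samples$sample_id))
    idx <- cbind(match(tbl$mutation_id, muts),
                 match(tbl$sample_id, samples$sample_id))
    mat[idx] <- tbl[[col]]
    mat
  }
  list(
    mutations = muts, samples = samples, n = n, m = m,
    alt = shape("alt_reads"), total = shape("total_reads"),
    cn = shape("total_cn"), multiplicity = shape("multiplicity"),
    purity = samples$purity, times = samples$time
  )
}
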