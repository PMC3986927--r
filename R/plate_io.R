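#' Read long-format kinetic plate data
#'
#' Reads a delimited text file (comma or tab, auto-detected) of plate
#' kinetics in long format, one row per (strain, condition, replicate, time)
#' observation, and returns one validated [pm_series] per
#' (strain, condition, replicate) triple, with rows sorted by time.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema Named character vector mapping the canonical column names
#'   `strain`, `condition`, `replicate`, `time_h`, `signal` to the file's
#'   column headers.
#' @return Named list of [pm_series], named by `strain/condition/rep<k>`,
#'   in sorted key order.
#' @seealso [write_kinetics()], [read_conditions()]
#' @export
read_kinetics <- function(path,
                          schema = c(strain = "strain",
                                     condition = "condition",
                                     replicate = "replicate",
                                     time_h = "time_h",
                                     signal = "signal")) {
  if (!file.exists(path)) stop("file not found: ", path)
  needed <- c("strain", "condition", "replicate", "time_h", "signal")
  if (!all(needed %in% names(schema)))
    stop("schema must map columns: ",
         paste(setdiff(needed, names(schema)), collapse = ", "))
  df <- read_delim_auto(path)
  missing <- setdiff(unname(schema[needed]), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  dat <- data.frame(strain = as.character(df[[schema[["strain"]]]]),
                    condition = as.character(df[[schema[["condition"]]]]),
                    replicate = df[[schema[["replicate"]]]],
                    time_h = as.numeric(df[[schema[["time_h"]]]]),
                    signal = as.numeric(df[[schema[["signal"]]]]),
                    stringsAsFactors = FALSE)
  key <- paste(dat$strain, dat$condition, dat$replicate, sep = "\r")
  dup <- duplicated(paste(key, dat$time_h, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate time point in series ",
         series_label(dat$strain[i], dat$condition[i], dat$replicate[i]),
         " at t = ", dat$time_h[i])
  }
  out <- lapply(split(dat, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    rep <- g$replicate[1L]
    if (!identical(rep, "mean")) rep <- as.numeric(rep)
    pm_series(g$strain[1L], g$condition[1L], rep, g$time_h, g$signal)
  })
  names(out) <- vapply(out, series_key, character(1L))
  out[order(names(out))]
}

# delimiter auto-detection: tab wins if present in the header line
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write kinetic series to a long-format TSV
#'
#' Inverse of [read_kinetics()]: serialises a collection of series as a
#' tab-delimited long table. Numeric values keep 15 significant digits so a
#' write/read round trip reproduces the series to well below 1e-6 relative.
#'
#' @param series List of [pm_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(series, path) {
  if (!length(series)) stop("no series to write")
  rows <- lapply(series, function(s) {
    data.frame(strain = s$strain_id, condition = s$condition_id,
               replicate = as.character(s$replicate),
               time_h = s$times, signal = s$signals,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$time_h <- format(df$time_h, digits = 15, trim = TRUE, scientific = FALSE)
  df$signal <- format(df$signal, digits = 15, trim = TRUE)
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # binary keeps LF line endings everywhere
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, as.character), list(sep = "\t")))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read and validate a stress-condition table
#'
#' The condition table links each stress condition to its matched unstressed
#' control and fixes the endpoint at which %RSI is read. Expected columns:
#' `condition_id`, `stressor`, `dose`, `unit`, `temperature_C`,
#' `endpoint_hours`, `control_id` (empty for controls). A missing/NA
#' endpoint defaults to 50 h, or 24 h when `temperature_C` is 40 (the 40
#' degree assays are truncated at 24 h because of evaporation).
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated `data.frame` of class `pm_conditions`.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_delim_auto(path)
  needed <- c("condition_id", "stressor", "dose", "unit", "temperature_C",
              "endpoint_hours", "control_id")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df <- df[, needed]
  df$condition_id <- as.character(df$condition_id)
  df$control_id <- as.character(df$control_id)
  df$control_id[is.na(df$control_id)] <- ""
  df$endpoint_hours <- as.numeric(df$endpoint_hours)
  as_pm_conditions(df)
}

#' Construct/validate a condition table from a data frame
#'
#' @param df Data frame with the columns described in [read_conditions()].
#' @return A `data.frame` of class `pm_conditions`.
#' @export
as_pm_conditions <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$condition_id))
    stop("duplicate condition_id: ",
         df$condition_id[duplicated(df$condition_id)][1L])
  na_ep <- is.na(df$endpoint_hours)
  df$endpoint_hours[na_ep] <- ifelse(df$temperature_C[na_ep] == 40, 24, 50)
  bad <- df$endpoint_hours <= 0
  if (any(bad))
    stop("condition ", df$condition_id[bad][1L], ": endpoint_hours must be > 0")
  is_stress <- nzchar(df$control_id)
  dangling <- is_stress & !(df$control_id %in% df$condition_id)
  if (any(dangling))
    stop("condition ", df$condition_id[dangling][1L],
         ": unknown control_id '", df$control_id[dangling][1L], "'")
  self_ref <- is_stress & df$control_id == df$condition_id
  if (any(self_ref))
    stop("condition ", df$condition_id[self_ref][1L],
         ": control_id refers to itself")
  rownames(df) <- NULL
  class(df) <- c("pm_conditions", "data.frame")
  df
}

#' Read a strain metadata table
#'
#' Expected columns `strain_id`, `species`, `origin`. Species outside the
#' study's controlled vocabulary are kept but reported with a warning.
#'
#' @param path Path to a CSV/TSV file.
#' @return A `data.frame` with validated unique, non-empty strain ids.
#' @export
read_strains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_delim_auto(path)
  needed <- c("strain_id", "species", "origin")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df$strain_id <- as.character(df$strain_id)
  if (any(!nzchar(df$strain_id) | is.na(df$strain_id)))
    stop("empty strain_id in ", path)
  if (anyDuplicated(df$strain_id))
    stop("duplicate strain_id: ", df$strain_id[duplicated(df$strain_id)][1L])
  vocab <- c("S. cerevisiae", "S. paradoxus", "S. kudriavzevii", "S. uvarum",
             "S. arboricolus", "S. castellii", "S. mikatae", "hybrid", "other")
  odd <- !(df$species %in% vocab)
  if (any(odd))
    warning("species outside controlled vocabulary: ",
            paste(unique(df$species[odd]), collapse = ", "))
  df
}

#' Write a tolerance-score table to TSV
#'
#' Serialises %RSI scores with a deterministic row order (condition, then
#' descending percent_rsi, then strain id) and 6 significant digits.
#'
#' @param scores A `pm_scores` data frame from [score_study()] (columns
#'   `strain_id`, `condition_id`, `rsi_stress`, `rsi_control`, `percent_rsi`,
#'   `low_control`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tolerance_table <- function(scores, path) {
  if (!NROW(scores)) stop("no scores to write")
  o <- order(scores$condition_id, -scores$percent_rsi, scores$strain_id)
  s <- scores[o, c("strain_id", "condition_id", "rsi_stress", "rsi_control",
                   "percent_rsi", "low_control"), drop = FALSE]
  for (col in c("rsi_stress", "rsi_control", "percent_rsi"))
    s[[col]] <- format(signif(s[[col]], 6), digits = 15, trim = TRUE)
  names(s)[names(s) == "low_control"] <- "low_control_flag"
  s$low_control_flag <- ifelse(s$low_control_flag, "TRUE", "FALSE")
  write_tsv(s, path)
  invisible(path)
}

#' Read back a tolerance-score table written by [write_tolerance_table()]
#'
#' @param path Path to the TSV.
#' @return A `pm_scores` data frame.
#' @export
read_tolerance_table <- function(path) {
  df <- read_delim_auto(path)
  names(df)[names(df) == "low_control_flag"] <- "low_control"
  df$low_control <- as.logical(df$low_control)
  class(df) <- c("pm_scores", "data.frame")
  df
}

#' Write a numeric matrix (e.g. the log-ratio matrix) as TSV
#'
#' First column `id` holds row names; values get 6 significant digits;
#' missing cells are written as `NA`.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat)))
    df[[colnames(mat)[j]]] <-
      ifelse(is.na(mat[, j]), "NA",
             format(signif(mat[, j], 6), digits = 15, trim = TRUE))
  write_tsv(df, path)
  invisible(path)
}

#' Convert a wide 96-well plate export to long format
#'
#' Helper for instrument-style wide tables (one `time_h` column plus one
#' column per well). `well_map` assigns each well column a strain,
#' condition and replicate.
#'
#' @param df Wide data frame with a `time_h` column.
#' @param well_map Data frame with columns `well`, `strain`, `condition`,
#'   `replicate`.
#' @return Long data frame with canonical columns, suitable for writing and
#'   re-reading via [write_kinetics()]/[read_kinetics()].
#' @export
wide_to_long <- function(df, well_map) {
  if (!"time_h" %in% names(df)) stop("wide table needs a time_h column")
  missing <- setdiff(well_map$well, names(df))
  if (length(missing))
    stop("wells absent from wide table: ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(well_map)), function(i) {
    w <- well_map[i, ]
    data.frame(strain = w$strain, condition = w$condition,
               replicate = w$replicate, time_h = df$time_h,
               signal = df[[w$well]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
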