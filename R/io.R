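#' Read a logger record table
#'
#' Reads one row per detection of a PIT-tagged individual at a logger.  The
#' file must be a CSV with header columns `individual_id`, `logger_id`,
#' `timestamp` (ISO-8601, parsed to minute resolution), `x` and `y` (metres).
#'
#' Rows whose `individual_id` is absent from `individuals` (when supplied) are
#' dropped with an informative message, echoing standard field-data
#' accounting.  Every `logger_id` must map to exactly one coordinate pair.
#'
#' @param path path to a CSV file.
#' @param individuals optional individual metadata tibble (see
#'   [read_individuals()]); used to drop detections of unknown individuals.
#' @return A tibble with columns `individual_id`, `logger_id`, `timestamp`
#'   (POSIXct, UTC, minute resolution), `x`, `y`, sorted by individual,
#'   logger and time.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("individual_id,logger_id,timestamp,x,y",
#'              "m1,L1,2015-03-01T23:10:00,10,20",
#'              "m2,L1,2015-03-01T23:12:00,10,20"), f)
#' read_records(f)
read_records <- function(path, individuals = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    logger_id = readr::col_character(),
    timestamp = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double()
  ))
  needed <- c("individual_id", "logger_id", "timestamp", "x", "y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Record file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ts <- as.POSIXct(rep(NA_character_, nrow(raw)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad)) {
    abort(sprintf("Unparseable timestamp(s) at data line(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  out <- raw |>
    mutate(timestamp = as.POSIXct(trunc(ts, "mins"))) |>
    select(all_of(needed[1:2]), "timestamp", "x", "y")
  if (!is.null(individuals)) {
    known <- out$individual_id %in% individuals$individual_id
    if (any(!known)) {
      inform(sprintf(
        "Dropped %d record(s) from %d unknown individual(s); %d record(s) retained.",
        sum(!known), length(unique(out$individual_id[!known])), sum(known)))
      out <- out[known, , drop = FALSE]
    }
  }
  validate_records(out)
  arrange(out, .data$individual_id, .data$logger_id, .data$timestamp)
}

validate_records <- function(records) {
  coords <- distinct(records, .data$logger_id, .data$x, .data$y)
  dup <- coords$logger_id[duplicated(coords$logger_id)]
  if (length(dup)) {
    abort(sprintf("Logger(s) with more than one coordinate pair: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  invisible(records)
}

#' Read individual metadata
#'
#' @param path CSV with columns `individual_id`, `sex` (`F`/`M`), `age`
#'   (`juvenile`/`adult`), `first_obs`, `last_obs` (ISO dates).
#' @return A validated tibble.
#' @export
read_individuals <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_character(),
    first_obs = readr::col_date(),
    last_obs = readr::col_date()
  ))
  if (any(out$first_obs > out$last_obs)) {
    abort("`first_obs` must not be later than `last_obs`.")
  }
  if (!all(out$sex %in% c("F", "M"))) abort("`sex` must be 'F' or 'M'.")
  if (!all(out$age %in% c("juvenile", "adult"))) {
    abort("`age` must be 'juvenile' or 'adult'.")
  }
  out
}

#' Read faecal sample metadata
#'
#' @param path CSV with columns `sample_id`, `individual_id`,
#'   `collection_date`.
#' @param individuals optional individual metadata for id validation.
#' @return A tibble.
#' @export
read_samples <- function(path, individuals = NULL) {
  out <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    individual_id = readr::col_character(),
    collection_date = readr::col_date()
  ))
  if (anyDuplicated(out$sample_id)) abort("Duplicated `sample_id` values.")
  if (!is.null(individuals)) {
    unknown <- setdiff(out$individual_id, individuals$individual_id)
    if (length(unknown)) {
      abort(sprintf("Sample(s) mapped to unknown individual(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  out
}

#' Read a pairwise kinship matrix
#'
#' @param path TSV whose first column holds individual ids and whose remaining
#'   columns form a square relatedness matrix with values in \[0, 1\].
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
read_kinship <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols())
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    abort("Kinship matrix columns must match the id column, in order.")
  }
  storage.mode(m) <- "double"
  stopifnot_square_symmetric(m, "kinship")
  if (any(m < 0 | m > 1, na.rm = TRUE)) abort("Kinship values must lie in [0, 1].")
  m
}

#' Write a kinship (or any square individual-by-individual) matrix
#' @param m symmetric matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "individual_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an ASV count table with its taxonomy
#'
#' @param counts_path TSV; first column `sample_id`, remaining columns one per
#'   ASV, cells non-negative integer read counts.
#' @param taxonomy_path TSV with columns `asv_id`, `Kingdom`, `Phylum`,
#'   `Class`, `Order`, `Family`.  Every ASV column in the count table must be
#'   covered.
#' @param samples optional sample metadata for id matching.
#' @return A [community_table()] in state `"raw"`.
#' @export
read_community <- function(counts_path, taxonomy_path, samples = NULL) {
  counts_df <- readr::read_tsv(counts_path, col_types = readr::cols())
  taxonomy <- readr::read_tsv(taxonomy_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- as.character(counts_df[[1]])
  storage.mode(counts) <- "double"
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("Negative count at sample '%s', ASV '%s'.",
                  rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  }
  if (any(counts != round(counts))) abort("Counts must be integers.")
  if (!is.null(samples)) {
    unknown <- setdiff(rownames(counts), samples$sample_id)
    if (length(unknown)) {
      abort(sprintf("Count rows with no sample metadata: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  community_table(counts, taxonomy)
}

#' Write the count matrix and taxonomy of a community table
#' @param ct a [community_table()].
#' @param counts_path,taxonomy_path output TSV paths.
#' @return `counts_path`, invisibly.
#' @export
write_community <- function(ct, counts_path, taxonomy_path) {
  df <- tibble::as_tibble(ct$counts, rownames = "sample_id")
  readr::write_tsv(df, counts_path)
  readr::write_tsv(ct$taxonomy, taxonomy_path)
  invisible(counts_path)
}

#' Write logger records
#' @param records record tibble from [read_records()] or [simulate_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- mutate(records,
                timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(out, path)
  invisible(path)
}
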