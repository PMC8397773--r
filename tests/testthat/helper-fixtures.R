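# Toy data builders shared across test files.  Everything is generated in
# code; no fixture files.

base_night <- as.Date("2015-03-01")

# records from a compact spec: list of c(id, logger, "HH:MM" [, day offset]);
# hours < 18 fall in the morning of the following calendar day
make_records <- function(rows, loggers = NULL) {
  if (is.null(loggers)) {
    loggers <- tibble::tibble(
      logger_id = c("L1", "L2", "L3"),
      x = c(0, 30, 60), y = c(0, 0, 0))
  }
  df <- purrr::map(rows, function(r) {
    hm <- as.numeric(strsplit(r[[3]], ":")[[1]])
    day <- if (length(r) >= 4) as.numeric(r[[4]]) else 0
    date <- base_night + day + if (hm[1] < 18) 1 else 0
    tibble::tibble(
      individual_id = r[[1]], logger_id = r[[2]],
      timestamp = as.POSIXct(paste(date), tz = "UTC") +
        hm[1] * 3600 + hm[2] * 60)
  }) |> dplyr::bind_rows()
  dplyr::left_join(df, loggers, by = "logger_id")
}

make_individuals <- function(ids, first = base_night, last = base_night + 30,
                             sex = NULL, age = NULL) {
  n <- length(ids)
  tibble::tibble(
    individual_id = ids,
    sex = sex %||% rep(c("F", "M"), length.out = n),
    age = age %||% rep("adult", n),
    first_obs = rep(as.Date(first), length.out = n),
    last_obs = rep(as.Date(last), length.out = n))
}

`%||%` <- rlang::`%||%`

# small community table: counts matrix with generic taxonomy
make_community <- function(counts, families = NULL) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("asv", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  tax <- tibble::tibble(
    asv_id = colnames(counts), Kingdom = "Bacteria", Phylum = "P1",
    Class = "C1", Order = "O1",
    Family = families %||% rep("FamA", ncol(counts)))
  community_table(counts, tax)
}

# quick small simulation used by several files
small_sim <- function(seed = 3, n_individuals = 15, n_nights = 30, ...) {
  simulate_study(sim_params(n_individuals = n_individuals,
                            n_nights = n_nights, seed = seed, ...))
}
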