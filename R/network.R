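#' Detect dyadic association events from logger records
#'
#' An *instance* is a (night, logger) combination, where a night runs from
#' `night_start_hour` on day *d* to `night_end_hour` on day *d + 1*.  A dyad
#' is associated at an instance when any detection of one member and any
#' detection of the other at that logger that night differ by at most
#' `window_minutes` (boundary inclusive; multiple qualifying detection pairs
#' in one instance still count once).  Per dyad the function returns
#'
#' * `x` - instances at which the pair was associated,
#' * `y_ab` - instances at which both were observed that night but not
#'   associated (same logger outside the window, or, under the default
#'   `"per_logger"` convention, each logger-night at which exactly one member
#'   appeared while the other was observed elsewhere the same night),
#' * `y_a`, `y_b` - instances at which one member was observed on a night the
#'   other was alive (between its first and last observation) but unobserved.
#'
#' All counts are restricted to nights inside both individuals' lifespans.
#'
#' @param records validated record tibble ([read_records()]).
#' @param individuals individual metadata with `first_obs`/`last_obs` dates
#'   defining lifespans ("known alive" spans).
#' @param window_minutes association window in minutes; may be a vector, in
#'   which case a named list of event tables is returned and the expensive
#'   instance scan is shared across windows.
#' @param night_start_hour,night_end_hour night bounds (defaults 18 and 6).
#' @param chain if `TRUE`, detections are grouped by single-linkage chaining
#'   (any two individuals connected through detections each within the window
#'   of the next are associated); default `FALSE` compares timestamps
#'   pairwise.
#' @param yab_convention `"per_logger"` (default) or `"per_night"`: whether
#'   same-night different-logger co-observations increment `y_ab` once per
#'   logger-night at which either member appears, or once per night.
#' @return A tibble of class `"assoc_events"` with columns `id_a`, `id_b`,
#'   `x`, `y_ab`, `y_a`, `y_b` (one row per unordered dyad), carrying
#'   `window_minutes` and the night bounds as attributes.  A named list of
#'   such tibbles when `window_minutes` has length > 1.
#' @export
detect_associations <- function(records, individuals, window_minutes,
                                night_start_hour = 18, night_end_hour = 6,
                                chain = FALSE,
                                yab_convention = c("per_logger", "per_night")) {
  yab_convention <- match.arg(yab_convention)
  night_len <- night_length_minutes(night_start_hour, night_end_hour)
  if (any(window_minutes > night_len)) {
    abort("`window_minutes` must not exceed the night length.")
  }
  ids <- individuals$individual_id
  n <- length(ids)
  windows <- sort(unique(window_minutes))
  nw <- length(windows)

  rec <- assign_nights(records, night_start_hour, night_end_hour)
  first_n <- as.Date(individuals$first_obs)
  last_n <- as.Date(individuals$last_obs)

  X <- lapply(windows, function(w) matrix(0, n, n))
  S <- matrix(0, n, n)        # both observed at the same instance
  YABx <- matrix(0, n, n)     # single-member instances on co-observed nights
  YA <- matrix(0, n, n)       # [i, j]: i observed, j alive but unobserved

  for (night in split(rec, rec$night)) {
    nd <- night$night[1]
    alive <- first_n <= nd & nd <= last_n
    night <- night[alive[match(night$individual_id, ids)], , drop = FALSE]
    if (!nrow(night)) next
    ii <- match(night$individual_id, ids)
    cvec <- numeric(n)          # instances at which each individual appears
    s_night <- matrix(0, n, n)  # same-instance co-detections this night
    for (grp in split(seq_len(nrow(night)), night$logger_id)) {
      gi <- ii[grp]
      gt <- night$minute[grp]
      u <- unique(gi)
      cvec[u] <- cvec[u] + 1
      if (length(u) < 2) next
      prs <- pair_index(length(u))
      for (k in seq_len(nrow(prs))) {
        a <- u[prs[k, 1]]; b <- u[prs[k, 2]]
        s_night[a, b] <- s_night[a, b] + 1
        s_night[b, a] <- s_night[b, a] + 1
        if (chain) {
          for (wi in seq_len(nw)) {
            if (chained_together(gt, gi, a, b, windows[wi])) {
              X[[wi]][a, b] <- X[[wi]][a, b] + 1
              X[[wi]][b, a] <- X[[wi]][b, a] + 1
            }
          }
        } else {
          gap <- min(abs(outer(gt[gi == a], gt[gi == b], "-")))
          for (wi in seq_len(nw)) {
            if (gap <= windows[wi]) {
              X[[wi]][a, b] <- X[[wi]][a, b] + 1
              X[[wi]][b, a] <- X[[wi]][b, a] + 1
            }
          }
        }
      }
    }
    obs <- cvec > 0
    M <- outer(alive, alive)
    both <- outer(obs, obs)
    singles <- outer(cvec, cvec, "+") - 2 * s_night
    if (yab_convention == "per_night") singles <- (singles > 0) * 1
    S <- S + M * both * s_night
    YABx <- YABx + M * both * singles
    YA <- YA + M * outer(cvec, !obs)
  }

  prs <- pair_index(n)
  build <- function(Xw, w) {
    ev <- tibble(
      id_a = ids[prs[, 1]], id_b = ids[prs[, 2]],
      x = Xw[prs], y_ab = (S - Xw)[prs] + YABx[prs],
      y_a = YA[prs], y_b = YA[prs[, c(2, 1), drop = FALSE]]
    )
    structure(ev, class = c("assoc_events", class(ev)),
              window_minutes = w, night_start_hour = night_start_hour,
              night_end_hour = night_end_hour, ids = ids,
              yab_convention = yab_convention)
  }
  out <- purrr::map2(X, as.list(windows), build)
  names(out) <- as.character(windows)
  if (length(window_minutes) == 1) out[[as.character(window_minutes)]] else out
}

# assign each record to its night; daytime records are dropped with a message
assign_nights <- function(records, night_start_hour, night_end_hour) {
  lt <- as.POSIXlt(records$timestamp, tz = "UTC")
  hour <- lt$hour
  evening <- hour >= night_start_hour
  morning <- hour < night_end_hour
  keep <- evening | morning
  if (any(!keep)) {
    inform(sprintf("Dropped %d daytime record(s) outside the night window.",
                   sum(!keep)))
  }
  records <- records[keep, , drop = FALSE]
  lt <- lt[keep]
  hour <- hour[keep]
  evening <- hour >= night_start_hour
  night <- as.Date(lt) - ifelse(evening, 0, 1)
  minute <- ifelse(evening, (hour - night_start_hour) * 60 + lt$min,
                   (24 - night_start_hour + hour) * 60 + lt$min)
  records$night <- night
  records$minute <- minute
  records
}

# are individuals a and b linked through a chain of detections, consecutive
# gaps each <= window?
chained_together <- function(times, inds, a, b, window) {
  o <- order(times)
  t_s <- times[o]; i_s <- inds[o]
  cl <- cumsum(c(0, diff(t_s) > window))
  any(vapply(unique(cl), function(k) {
    members <- i_s[cl == k]
    a %in% members && b %in% members
  }, logical(1)))
}

assoc_matrix <- function(m, kind, window_minutes) {
  stopifnot_square_symmetric(m, "association matrix")
  structure(m, kind = kind, window_minutes = window_minutes,
            class = c("assoc_matrix", class(m)))
}

#' Lifespan-adjusted Simple Ratio Index
#'
#' For each dyad, \eqn{I = X / (X + y_{AB} + y_A + y_B)}: the proportion of
#' relevant instances at which the pair was observed associated, with the
#' denominator restricted to nights when both were known alive, correcting
#' for unequal lifespan overlap.  Dyads with a zero denominator (no lifespan
#' overlap with observations) get value 0 and are flagged.
#'
#' @param events an `"assoc_events"` table from [detect_associations()].
#' @return A symmetric `"assoc_matrix"` (kind `"SRI"`, values in \[0, 1\])
#'   with a logical `"no_overlap"` attribute matrix.
#' @export
adjusted_sri <- function(events) {
  ids <- attr(events, "ids")
  denom <- events$x + events$y_ab + events$y_a + events$y_b
  val <- ifelse(denom > 0, events$x / denom, 0)
  m <- dyads_to_matrix(events$id_a, events$id_b, val, ids)
  out <- assoc_matrix(m, "SRI", attr(events, "window_minutes"))
  attr(out, "no_overlap") <-
    dyads_to_matrix(events$id_a, events$id_b, denom == 0, ids) > 0
  out
}

#' Binary association index
#'
#' 1 when the dyad was observed associated at least once, else 0.
#'
#' @inheritParams adjusted_sri
#' @return A symmetric `"assoc_matrix"` (kind `"BI"`, values in \{0, 1\}).
#' @export
binary_index <- function(events) {
  ids <- attr(events, "ids")
  m <- dyads_to_matrix(events$id_a, events$id_b, as.numeric(events$x >= 1), ids)
  assoc_matrix(m, "BI", attr(events, "window_minutes"))
}

#' Spatial summary of individual space use
#'
#' Mean logger coordinates per individual, the pairwise Euclidean distance
#' matrix (metres), and for each individual the distance to its nearest
#' neighbour and (when an SRI matrix is supplied) to its closest social
#' partner (nearest individual with SRI > 0).
#'
#' @param records record tibble.
#' @param min_records individuals with fewer records are excluded with a
#'   message (set to 34 to mirror a stringent field threshold).
#' @param sri optional `"assoc_matrix"` used for closest-partner distances.
#' @return A list of class `"spatial_summary"`: `coords` tibble
#'   (`individual_id`, `x`, `y`, `n_records`, `nearest_neighbour_m`,
#'   `closest_partner_m`) and `distance` matrix.
#' @export
spatial_summary <- function(records, min_records = 1, sri = NULL) {
  coords <- records |>
    group_by(.data$individual_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y), n_records = n(),
              .groups = "drop")
  low <- coords$n_records < min_records
  if (any(low)) {
    inform(sprintf("Excluded %d individual(s) below the %d-record threshold: %s",
                   sum(low), min_records,
                   paste(coords$individual_id[low], collapse = ", ")))
    coords <- coords[!low, , drop = FALSE]
  }
  dmat <- as.matrix(dist(cbind(coords$x, coords$y)))
  dimnames(dmat) <- list(coords$individual_id, coords$individual_id)
  nn <- apply(dmat + diag(Inf, nrow(dmat)), 1, min)
  partner <- rep(NA_real_, nrow(coords))
  if (!is.null(sri)) {
    shared <- intersect(coords$individual_id, rownames(sri))
    for (i in seq_len(nrow(coords))) {
      id <- coords$individual_id[i]
      if (!id %in% shared) next
      mates <- setdiff(shared[sri[id, shared] > 0], id)
      if (length(mates)) partner[i] <- min(dmat[id, mates])
    }
  }
  coords$nearest_neighbour_m <- if (nrow(coords) > 1) unname(nn) else NA_real_
  coords$closest_partner_m <- partner
  structure(list(coords = coords, distance = dmat),
            class = "spatial_summary")
}

#' Mantel correlation between two association matrices
#'
#' Pearson correlation of the upper triangles with a permutation p-value,
#' used to quantify how networks built with different edge definitions decay
#' in similarity.
#'
#' @param m1,m2 `"assoc_matrix"` objects over the same individuals.
#' @param n_perm number of matrix permutations.
#' @param seed integer seed.
#' @return A tibble with `r`, `p`, `n_perm`, `seed`.
#' @export
compare_networks <- function(m1, m2, n_perm = 999, seed = 1) {
  if (!setequal(rownames(m1), rownames(m2))) {
    abort("The two matrices must cover the same individuals.")
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  fit <- withr::with_seed(seed,
    vegan::mantel(as.dist(m1), as.dist(m2), permutations = n_perm))
  tibble(r = unname(fit$statistic), p = unname(fit$signif),
         n_perm = n_perm, seed = seed)
}

#' Summary statistics of an association network
#'
#' @param m an `"assoc_matrix"`.
#' @return A tibble with `n_individuals`, `n_edges`, `density` (nonzero edges
#'   over possible dyads), `mean_weight` and `sd_weight` of nonzero edges.
#' @export
network_summary <- function(m) {
  w <- upper_tri_vec(unclass(m))
  nz <- w[w > 0]
  tibble(n_individuals = nrow(m), n_edges = length(nz),
         density = if (length(w)) length(nz) / length(w) else NA_real_,
         mean_weight = if (length(nz)) mean(nz) else NA_real_,
         sd_weight = if (length(nz) > 1) sd(nz) else NA_real_,
         kind = attr(m, "kind") %||% NA_character_,
         window_minutes = attr(m, "window_minutes") %||% NA_real_)
}
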