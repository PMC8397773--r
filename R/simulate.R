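#' Parameters of the synthetic study generator
#'
#' Bundles every knob of the generative model behind the synthetic logger
#' stream, population and gut-community dynamics.  Defaults are the
#' package's study conditions: a ~2.25 ha plot monitored with 9 loggers over
#' 60 nights, 40 individuals with 15 m home-range kernels making 3 logger
#' visits per night, 5% of dyads socially affiliated (about two strong
#' associates per individual), presence/absence
#' transmission of "contact-only" bacterial families at synchronized (<= 2
#' min) co-visits, and spatially structured colonisation of "environmental"
#' families.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_loggers number of loggers, laid out on a regular grid.
#' @param grid_extent side of the square study plot, metres.
#' @param n_nights number of logging nights.
#' @param home_range_sd sd (metres) of the Gaussian kernel linking an
#'   individual's home-range centre to its logger visit probabilities.
#' @param visit_rate expected independent logger visits per individual per
#'   night.
#' @param covisit_rate expected synchronized co-visits per night for a dyad
#'   with affinity 1 (scales linearly with affinity).
#' @param pair_affinity optional symmetric zero-diagonal matrix of co-visit
#'   propensities in \[0, 1\]; generated at [simulate_population()] time when
#'   `NULL`.
#' @param affinity_density fraction of dyads given nonzero affinity when
#'   `pair_affinity` is generated.
#' @param transmission_strength per-contact-event probability that a
#'   contact-only ASV present in one member and absent in the other
#'   transfers (beta_social >= 0).
#' @param spatial_strength per-night colonisation probability scale for
#'   environmental ASVs at zero distance from their source (beta_space).
#' @param sexdep `"none"` or `"male_biased"`; under `"male_biased"`,
#'   transmission probability for female-female contacts is multiplied by 0.
#' @param n_asvs,n_families size of the ASV pool and its family partition
#'   (families alternate between the contact-only and environmental guilds).
#' @param baseline_richness ASVs seeded into each individual at birth.
#' @param drift_rate per-night loss probability of a resident ASV.
#' @param samples_per_individual faecal samples per individual, evenly
#'   spread over its lifespan.
#' @param seed integer seed; all generator stages are deterministic given it.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_individuals = 40, n_loggers = 9, grid_extent = 150,
                       n_nights = 60, home_range_sd = 15, visit_rate = 3,
                       covisit_rate = 0.5, pair_affinity = NULL,
                       affinity_density = 0.05, transmission_strength = 0.2,
                       spatial_strength = 0.02,
                       sexdep = c("none", "male_biased"), n_asvs = 200,
                       n_families = 10, baseline_richness = 40,
                       drift_rate = 0.01, samples_per_individual = 3,
                       seed = 1) {
  sexdep <- match.arg(sexdep)
  if (n_individuals < 2) abort("`n_individuals` must be at least 2.")
  if (n_families > n_asvs) abort("`n_families` must not exceed `n_asvs`.")
  if (any(c(visit_rate, covisit_rate, transmission_strength,
            spatial_strength, drift_rate) < 0)) {
    abort("Rates must be non-negative.")
  }
  if (!is.null(pair_affinity)) {
    stopifnot_square_symmetric(pair_affinity, "pair_affinity")
    if (any(diag(pair_affinity) != 0)) {
      abort("`pair_affinity` must have a zero diagonal.")
    }
    if (any(pair_affinity < 0 | pair_affinity > 1)) {
      abort("`pair_affinity` values must lie in [0, 1].")
    }
  }
  structure(as.list(environment()), class = "sim_params")
}

sim_base_date <- as.Date("2015-01-01")

#' Simulate a monitored population
#'
#' Draws home-range centres uniformly on the plot, sexes Bernoulli(0.5),
#' ages, lifespans covering overlapping subsets of nights, a regular logger
#' layout, a two-generation pedigree-based kinship matrix (values 0, 0.25,
#' 0.5) and - independently of kinship - the dyadic affinity matrix used for
#' synchronized co-visits.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `"sim_population"`: `individuals` (with
#'   `first_obs`/`last_obs` dates and night indices), `kinship`, `loggers`,
#'   `centres`, `pair_affinity`, `params`.
#' @export
simulate_population <- function(params) {
  p <- params
  withr::with_seed(p$seed, {
    n <- p$n_individuals
    ids <- sprintf("m%03d", seq_len(n))
    centres <- tibble(individual_id = ids,
                      x = runif(n, 0, p$grid_extent),
                      y = runif(n, 0, p$grid_extent))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- sample(c("juvenile", "adult"), n, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (p$n_nights > 0) {
      head_n <- max(1L, round(0.1 * p$n_nights))
      first_night <- sample(seq_len(head_n), n, replace = TRUE)
      last_night <- sample(seq(max(1L, ceiling(0.9 * p$n_nights)),
                               p$n_nights), n, replace = TRUE)
      last_night <- pmax(last_night, first_night)
    } else {
      first_night <- last_night <- rep(1L, n)
    }
    individuals <- tibble(
      individual_id = ids, sex = sex, age = age,
      first_obs = sim_base_date + first_night - 1,
      last_obs = sim_base_date + last_night - 1,
      first_night = first_night, last_night = last_night)

    # two-generation pedigree: litters share both parents (full sibs, 0.5);
    # litters can share a father (half sibs, 0.25); everyone else unrelated
    n_litters <- max(2L, ceiling(n / 3))
    litter <- sample(n_litters, n, replace = TRUE)
    mother <- seq_len(n_litters)
    father <- sample(max(1L, ceiling(n_litters * 0.6)), n_litters,
                     replace = TRUE)
    kinship <- kinship_from_parents(mother[litter], father[litter])
    dimnames(kinship) <- list(ids, ids)

    affinity <- p$pair_affinity
    if (is.null(affinity)) {
      affinity <- matrix(0, n, n)
      prs <- pair_index(n)
      on <- runif(nrow(prs)) < p$affinity_density
      val <- ifelse(on, runif(nrow(prs), 0.2, 1), 0)
      affinity[prs] <- val
      affinity[prs[, c(2, 1), drop = FALSE]] <- val
    }
    dimnames(affinity) <- list(ids, ids)

    g <- ceiling(sqrt(p$n_loggers))
    gxy <- expand.grid(gx = (seq_len(g) - 0.5) / g,
                       gy = (seq_len(g) - 0.5) / g)[seq_len(p$n_loggers), ]
    loggers <- tibble(logger_id = sprintf("L%02d", seq_len(p$n_loggers)),
                      x = gxy$gx * p$grid_extent, y = gxy$gy * p$grid_extent)

    structure(list(individuals = individuals, kinship = kinship,
                   loggers = loggers, centres = centres,
                   pair_affinity = affinity, params = p),
              class = "sim_population")
  })
}

#' Kinship from parent identities
#'
#' Sharing both parents gives 0.5 (full sibs), exactly one 0.25 (half sibs),
#' none 0; the diagonal is set to 1 (ignored downstream).
#'
#' @param mother,father parent identifiers, one per individual.
#' @return Symmetric kinship matrix.
#' @export
kinship_from_parents <- function(mother, father) {
  n <- length(mother)
  shared <- outer(mother, mother, "==") + outer(father, father, "==")
  k <- matrix(c(0, 0.25, 0.5)[shared + 1], n, n)
  diag(k) <- 1
  k
}

#' Simulate a nightly logger record stream
#'
#' Each alive individual makes Poisson(`visit_rate`) independent logger
#' visits per night, choosing loggers with probability decaying in distance
#' from its home-range centre (Gaussian kernel, sd `home_range_sd`), at
#' uniform minutes within the 6 pm-6 am night.  Dyads with affinity
#' \eqn{a_{ij}} additionally make Poisson(`covisit_rate` \eqn{\times a_{ij}})
#' synchronized co-visits: both members detected at the same logger within
#' 2 minutes.  These injected co-visit events are the ground-truth contact
#' structure and are attached as the `"contacts"` attribute.
#'
#' @param params a [sim_params()] object.
#' @param population a [simulate_population()] result.
#' @return A record tibble (`individual_id`, `logger_id`, `timestamp`, `x`,
#'   `y`) with attributes `contacts` (tibble `night`, `id_a`, `id_b`) and
#'   `loggers`.
#' @export
simulate_records <- function(params, population) {
  p <- params
  pop <- population
  ids <- pop$individuals$individual_id
  n <- length(ids)
  empty <- tibble(individual_id = character(), logger_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  x = double(), y = double())
  withr::with_seed(p$seed + 1L, {
    if (p$n_nights == 0) {
      out <- empty
      attr(out, "contacts") <- tibble(night = integer(), id_a = character(),
                                      id_b = character())
      attr(out, "loggers") <- pop$loggers
      return(out)
    }
    d2 <- outer(pop$centres$x, pop$loggers$x, "-")^2 +
      outer(pop$centres$y, pop$loggers$y, "-")^2
    K <- exp(-d2 / (2 * p$home_range_sd^2))
    K <- K / pmax(rowSums(K), .Machine$double.eps)
    prs <- pair_index(n)
    aff <- pop$pair_affinity[prs]
    night_len <- 720L
    acc_i <- list(); acc_l <- list(); acc_t <- list(); acc_m <- list()
    co_n <- list(); co_a <- list(); co_b <- list()
    push <- function(i, l, t, m) {
      k <- length(acc_i) + 1
      acc_i[[k]] <<- i; acc_l[[k]] <<- l
      acc_t[[k]] <<- rep.int(t, length(i)); acc_m[[k]] <<- m
    }
    for (t in seq_len(p$n_nights)) {
      alive <- pop$individuals$first_night <= t &
        t <= pop$individuals$last_night
      nv <- rpois(n, p$visit_rate) * alive
      if (any(nv > 0)) {
        who <- rep(seq_len(n), nv)
        lg <- unlist(lapply(which(nv > 0), function(i) {
          sample.int(p$n_loggers, nv[i], replace = TRUE, prob = K[i, ])
        }))
        push(who, lg, t,
             sample.int(night_len, length(who), replace = TRUE) - 1L)
      }
      both_alive <- alive[prs[, 1]] & alive[prs[, 2]]
      nco <- rpois(nrow(prs), p$covisit_rate * aff) * both_alive
      hot <- which(nco > 0)
      if (length(hot)) {
        ev_k <- rep.int(hot, nco[hot])
        ev_i <- prs[ev_k, 1]; ev_j <- prs[ev_k, 2]
        ev_l <- vapply(ev_k, function(k) {
          wt <- K[prs[k, 1], ] * K[prs[k, 2], ]
          if (sum(wt) == 0) wt <- rep(1, p$n_loggers)
          sample.int(p$n_loggers, 1, prob = wt)
        }, integer(1))
        base <- sample.int(night_len - 2L, length(ev_k), replace = TRUE) - 1L
        off <- sample.int(3L, length(ev_k), replace = TRUE) - 1L  # <= 2 min
        push(c(ev_i, ev_j), c(ev_l, ev_l), t, c(base, base + off))
        kk <- length(co_n) + 1
        co_n[[kk]] <- rep.int(t, length(ev_k))
        co_a[[kk]] <- ids[ev_i]; co_b[[kk]] <- ids[ev_j]
      }
    }
    contacts <- tibble(night = as.integer(unlist(co_n)),
                       id_a = as.character(unlist(co_a)),
                       id_b = as.character(unlist(co_b)))
    if (!length(acc_i)) {
      out <- empty
    } else {
      ri <- unlist(acc_i); rl <- unlist(acc_l)
      rt <- unlist(acc_t); rm <- unlist(acc_m)
      out <- tibble(
        individual_id = ids[ri],
        logger_id = pop$loggers$logger_id[rl],
        timestamp = as.POSIXct(sim_base_date, tz = "UTC") +
          (rt - 1) * 86400 + (18 * 60 + rm) * 60,
        x = pop$loggers$x[rl], y = pop$loggers$y[rl]) |>
        arrange(.data$individual_id, .data$logger_id, .data$timestamp)
    }
    attr(out, "contacts") <- contacts
    attr(out, "loggers") <- pop$loggers
    out
  })
}

#' Ground-truth contact events of a simulated record stream
#' @param records a [simulate_records()] result.
#' @return The injected co-visit event tibble.
#' @export
sim_contacts <- function(records) {
  ct <- attr(records, "contacts")
  if (is.null(ct)) abort("`records` carries no ground-truth contacts.")
  ct
}

#' Ground-truth contact-rate matrix
#' @param contacts contact tibble (or a records object carrying one).
#' @param ids individual ids fixing matrix order.
#' @return Symmetric matrix of total synchronized co-visit counts.
#' @export
contact_matrix <- function(contacts, ids) {
  if (is.data.frame(contacts) && !is.null(attr(contacts, "contacts"))) {
    contacts <- attr(contacts, "contacts")
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(contacts)) {
    tab <- contacts |> dplyr::count(.data$id_a, .data$id_b)
    m[cbind(tab$id_a, tab$id_b)] <- tab$n
    m[cbind(tab$id_b, tab$id_a)] <- tab$n
  }
  m
}

#' Simulate gut-community dynamics and faecal sampling
#'
#' Each individual starts from a baseline community (`baseline_richness`
#' ASVs drawn by family-structured weights, giving consistent individual
#' signatures).  Per night: contact-only-guild ASVs transfer between the
#' members of each ground-truth contact event with probability
#' `transmission_strength` (female-female events transmit nothing under
#' `sexdep = "male_biased"`); environmental-guild ASVs colonise from fixed
#' spatial sources with probability `spatial_strength` times a Gaussian
#' kernel of the individual-source distance; resident ASVs drop out at
#' `drift_rate`.  Faecal samples are multinomial draws (depth log-normal
#' around 10^4) at `samples_per_individual` dates per individual.
#'
#' @param params a [sim_params()] object.
#' @param population a [simulate_population()] result.
#' @param contacts ground-truth contact events: the tibble from
#'   [sim_contacts()] or a [simulate_records()] result carrying it.
#' @return A list of class `"sim_microbiota"`: `community` (a raw
#'   [community_table()]), `samples` (sample metadata tibble) and
#'   `ground_truth` (list: `contact_matrix`, `guilds` tibble mapping family
#'   to guild, `trajectories` presence matrices at sampling dates).
#' @export
simulate_microbiota <- function(params, population, contacts) {
  p <- params
  pop <- population
  if (is.data.frame(contacts) && !is.null(attr(contacts, "contacts"))) {
    contacts <- attr(contacts, "contacts")
  }
  ids <- pop$individuals$individual_id
  n <- length(ids)
  withr::with_seed(p$seed + 2L, {
    asv_ids <- sprintf("ASV%04d", seq_len(p$n_asvs))
    fam <- sort(rep_len(seq_len(p$n_families), p$n_asvs))
    fam_name <- sprintf("Fam%02d", fam)
    guild_of_family <- ifelse(seq_len(p$n_families) %% 2 == 1,
                              "contact", "environmental")
    guild <- guild_of_family[fam]
    taxonomy <- tibble(asv_id = asv_ids, Kingdom = "Bacteria",
                       Phylum = ifelse(guild == "contact", "P_contact",
                                       "P_env"),
                       Class = "C1", Order = "O1", Family = fam_name)
    w <- rlnorm(p$n_asvs, 0, 1.5)
    pref <- matrix(stats::rgamma(n * p$n_families, shape = 0.5), n,
                   p$n_families)
    P <- matrix(FALSE, n, p$n_asvs, dimnames = list(ids, asv_ids))
    for (i in seq_len(n)) {
      pr <- w * pref[i, fam]
      picks <- sample.int(p$n_asvs, min(p$baseline_richness, p$n_asvs),
                          prob = pr)
      P[i, picks] <- TRUE
    }
    env_idx <- which(guild == "environmental")
    contact_idx <- which(guild == "contact")
    src <- cbind(runif(length(env_idx), 0, p$grid_extent),
                 runif(length(env_idx), 0, p$grid_extent))
    d2 <- outer(pop$centres$x, src[, 1], "-")^2 +
      outer(pop$centres$y, src[, 2], "-")^2
    colprob <- p$spatial_strength * exp(-d2 / (2 * (2 * p$home_range_sd)^2))

    sex <- pop$individuals$sex
    # sampling starts after a burn-in third of each lifespan, so sampled
    # communities reflect accumulated transmission history rather than the
    # asocial baseline state
    sample_nights <- purrr::map(seq_len(n), function(i) {
      a <- pop$individuals$first_night[i]
      b <- pop$individuals$last_night[i]
      unique(round(seq(a + (b - a) / 3, b,
                       length.out = p$samples_per_individual)))
    })
    by_night <- if (nrow(contacts)) split(contacts, contacts$night) else list()
    srows <- list(); scounts <- list(); straj <- list()
    n_nights_eff <- max(1L, p$n_nights)
    for (t in seq_len(n_nights_eff)) {
      alive <- pop$individuals$first_night <= t &
        t <= pop$individuals$last_night
      ev <- by_night[[as.character(t)]]
      if (!is.null(ev) && p$transmission_strength > 0) {
        for (k in seq_len(nrow(ev))) {
          i <- match(ev$id_a[k], ids); j <- match(ev$id_b[k], ids)
          if (p$sexdep == "male_biased" && sex[i] == "F" && sex[j] == "F")
            next
          gain_j <- contact_idx[P[i, contact_idx] & !P[j, contact_idx]]
          if (length(gain_j)) {
            tr <- gain_j[runif(length(gain_j)) < p$transmission_strength]
            P[j, tr] <- TRUE
          }
          gain_i <- contact_idx[P[j, contact_idx] & !P[i, contact_idx]]
          if (length(gain_i)) {
            tr <- gain_i[runif(length(gain_i)) < p$transmission_strength]
            P[i, tr] <- TRUE
          }
        }
      }
      if (p$spatial_strength > 0 && any(alive)) {
        gains <- matrix(runif(sum(alive) * length(env_idx)), sum(alive)) <
          colprob[alive, , drop = FALSE]
        P[alive, env_idx] <- P[alive, env_idx, drop = FALSE] | gains
      }
      if (p$drift_rate > 0 && any(alive)) {
        keep <- matrix(runif(sum(alive) * p$n_asvs), sum(alive)) >=
          p$drift_rate
        P[alive, ] <- P[alive, , drop = FALSE] & keep
      }
      for (i in which(vapply(sample_nights,
                             function(s) t %in% s, logical(1)))) {
        present <- which(P[i, ])
        depth <- max(100L, round(rlnorm(1, log(1e4), 0.3)))
        cnt <- numeric(p$n_asvs)
        if (length(present)) {
          ab <- w[present] * rlnorm(length(present), 0, 0.5)
          cnt[present] <- rmultinom(1, depth, ab)[, 1]
        }
        srows[[length(srows) + 1]] <- tibble(
          individual_id = ids[i], night = t,
          collection_date = sim_base_date + t - 1)
        scounts[[length(scounts) + 1]] <- cnt
        straj[[length(straj) + 1]] <- P[i, ]
      }
    }
    samples <- bind_rows(srows)
    samples$sample_id <- sprintf("s%03d", seq_len(nrow(samples)))
    samples <- select(samples, "sample_id", "individual_id",
                      "collection_date", "night")
    counts <- do.call(rbind, scounts)
    dimnames(counts) <- list(samples$sample_id, asv_ids)
    traj <- do.call(rbind, straj)
    rownames(traj) <- samples$sample_id
    ground_truth <- list(
      contact_matrix = contact_matrix(contacts, ids),
      guilds = tibble(family = sprintf("Fam%02d", seq_len(p$n_families)),
                      guild = guild_of_family),
      trajectories = traj)
    structure(list(community = community_table(counts, taxonomy),
                   samples = samples, ground_truth = ground_truth),
              class = "sim_microbiota")
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper chaining [simulate_population()],
#' [simulate_records()] and [simulate_microbiota()].
#'
#' @param params a [sim_params()] object.
#' @return A list with `params`, `population`, `individuals`, `kinship`,
#'   `records`, `contacts`, `community`, `samples`, `ground_truth`.
#' @export
simulate_study <- function(params) {
  pop <- simulate_population(params)
  rec <- simulate_records(params, pop)
  mic <- simulate_microbiota(params, pop, rec)
  list(params = params, population = pop, individuals = pop$individuals,
       kinship = pop$kinship, records = rec, contacts = sim_contacts(rec),
       community = mic$community, samples = mic$samples,
       ground_truth = mic$ground_truth)
}
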