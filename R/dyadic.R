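#' Assemble the dyadic sample-pair table
#'
#' One row per unordered between-individual sample pair, combining the
#' microbiota similarity response with every dyadic covariate: social
#' association strength, spatial distance, sampling interval, kinship, sex
#' and age similarity, and the dyad sex category.  Spatial distance and
#' sampling interval are min-max scaled to \[0, 1\] over the table so all
#' model estimates are comparable; the raw values are kept alongside.
#'
#' @param similarity sample-by-sample `"similarity_matrix"`; Bray-Curtis
#'   dissimilarities are converted to similarity (1 - dissimilarity) so the
#'   response direction matches the Jaccard Index.
#' @param sri individual-by-individual `"assoc_matrix"` (SRI or BI).
#' @param spatial a [spatial_summary()] or an individual distance matrix.
#' @param kinship symmetric kinship matrix.
#' @param individuals individual metadata (sex, age).
#' @param samples sample metadata mapping samples to individuals with
#'   collection dates.
#' @return A tibble with one row per between-individual sample pair:
#'   `sample_a`, `sample_b`, `id_a`, `id_b`, `similarity`,
#'   `social_strength`, `spatial_distance`, `sampling_interval`, `kinship`,
#'   `sex_same`, `age_same`, `dyad_sex_category`, plus unscaled
#'   `spatial_distance_m` and `sampling_interval_days`.  Attributes record
#'   the response metric and network window.
#' @export
build_dyad_table <- function(similarity, sri, spatial, kinship, individuals,
                             samples) {
  unknown <- setdiff(samples$individual_id, individuals$individual_id)
  if (length(unknown)) {
    abort(sprintf("Sample(s) mapped to unknown individual(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  dmat <- if (inherits(spatial, "spatial_summary")) spatial$distance else spatial
  metric <- attr(similarity, "metric") %||% "jaccard_index"
  sim <- unclass(similarity)
  if (metric == "bray_curtis_dissimilarity") sim <- 1 - sim

  samples <- samples[samples$sample_id %in% rownames(sim), , drop = FALSE]
  prs <- pair_index(nrow(samples))
  sa <- samples$sample_id[prs[, 1]]
  sb <- samples$sample_id[prs[, 2]]
  ia <- samples$individual_id[prs[, 1]]
  ib <- samples$individual_id[prs[, 2]]
  between <- ia != ib
  sa <- sa[between]; sb <- sb[between]; ia <- ia[between]; ib <- ib[between]

  covered <- ia %in% rownames(dmat) & ib %in% rownames(dmat) &
    ia %in% rownames(kinship) & ib %in% rownames(kinship) &
    ia %in% rownames(sri) & ib %in% rownames(sri)
  if (any(!covered)) {
    inform(sprintf(
      "Dropped %d sample pair(s) whose individuals lack spatial, kinship or network coverage.",
      sum(!covered)))
    sa <- sa[covered]; sb <- sb[covered]; ia <- ia[covered]; ib <- ib[covered]
  }
  meta <- individuals[match(ia, individuals$individual_id), ]
  metb <- individuals[match(ib, individuals$individual_id), ]
  dates <- samples$collection_date[match(sa, samples$sample_id)]
  datesb <- samples$collection_date[match(sb, samples$sample_id)]
  n_male <- (meta$sex == "M") + (metb$sex == "M")
  out <- tibble(
    sample_a = sa, sample_b = sb, id_a = ia, id_b = ib,
    similarity = sim[cbind(sa, sb)],
    social_strength = sri[cbind(ia, ib)],
    spatial_distance_m = dmat[cbind(ia, ib)],
    sampling_interval_days = abs(as.numeric(datesb - dates)),
    kinship = kinship[cbind(ia, ib)],
    sex_same = as.numeric(meta$sex == metb$sex),
    age_same = as.numeric(meta$age == metb$age),
    dyad_sex_category = c("FF", "MF", "MM")[n_male + 1]
  )
  out$spatial_distance <- minmax_scale(out$spatial_distance_m)
  out$sampling_interval <- minmax_scale(out$sampling_interval_days)
  structure(out, metric = metric,
            window_minutes = attr(sri, "window_minutes"),
            network_kind = attr(sri, "kind"))
}

minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

# reconstruct the individual-level pairwise structure of a dyadic covariate
dyad_covariate_matrix <- function(dyads, col, ids) {
  first <- dyads[!duplicated(paste(dyads$id_a, dyads$id_b)), ]
  dyads_to_matrix(first$id_a, first$id_b, first[[col]], ids,
                  fill = NA_real_)
}

# shared engine: logit response, OLS fit, node-label permutation inference.
# `covariate_cols` are individual-level structures permuted with identities;
# `fixed_cols` are sample-level covariates that never permute; `extra` can
# append permutation-dependent design columns (sex-interaction model).
dyadic_perm_engine <- function(dyads, covariate_cols, n_perm, seed, epsilon,
                               variant, fixed_cols = character(),
                               extra = NULL) {
  if (nrow(dyads) < 3) abort("Too few dyadic rows to fit a model.")
  y <- logit_clamp(dyads$similarity, epsilon)
  if (var(y) == 0) abort("Constant response; nothing to fit.")
  ids <- sort(unique(c(dyads$id_a, dyads$id_b)))
  n_ind <- length(ids)
  ia <- match(dyads$id_a, ids)
  ib <- match(dyads$id_b, ids)
  mats <- lapply(covariate_cols, function(cl)
    dyad_covariate_matrix(dyads, cl, ids))
  names(mats) <- covariate_cols

  all_cols <- c(covariate_cols, fixed_cols)
  values <- lapply(all_cols, function(cl) dyads[[cl]])
  names(values) <- all_cols
  constant <- vapply(values, function(v) var(v) == 0, logical(1))
  keep <- setdiff(covariate_cols, all_cols[constant])
  keep_fixed <- setdiff(fixed_cols, all_cols[constant])
  nonconst <- c(keep, keep_fixed)
  if (length(nonconst) > 1) {
    cm <- suppressWarnings(cor(as.data.frame(values[nonconst])))
    cm[!upper.tri(cm)] <- 0
    bad <- which(abs(cm) > 0.999, arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf("Collinear covariate pair: %s and %s",
                    nonconst[bad[1, 1]], nonconst[bad[1, 2]]))
    }
  }
  Xf <- if (length(keep_fixed)) {
    mf <- vapply(keep_fixed, function(cl) dyads[[cl]], numeric(nrow(dyads)))
    colnames(mf) <- keep_fixed
    mf
  } else NULL
  build_X <- function(perm) {
    pia <- perm[ia]; pib <- perm[ib]
    Xc <- vapply(keep, function(cl) mats[[cl]][cbind(pia, pib)],
                 numeric(length(ia)))
    if (!length(keep)) Xc <- matrix(numeric(0), length(ia), 0)
    Xp <- if (!is.null(extra)) extra$builder(pia, pib) else NULL
    cbind(`(intercept)` = 1, Xc, Xf, Xp)
  }
  identity_perm <- seq_len(n_ind)
  X_obs <- build_X(identity_perm)
  obs <- ols_beta(X_obs, y)
  names(obs) <- colnames(X_obs)
  perm_mat <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      ols_beta(build_X(sample.int(n_ind)), y)
    }, numeric(length(obs))))
  })
  colnames(perm_mat) <- names(obs)

  terms <- setdiff(names(obs), "(intercept)")
  coefs <- purrr::map(terms, function(tm) {
    ci <- perm_interval(obs[[tm]], perm_mat[, tm])
    tibble(term = tm, estimate = obs[[tm]],
           p_perm = perm_pvalue(obs[[tm]], perm_mat[, tm]),
           conf_low = ci[1], conf_high = ci[2], flag = NA_character_)
  }) |> bind_rows()
  if (any(constant)) {
    coefs <- bind_rows(coefs, tibble(
      term = all_cols[constant], estimate = 0, p_perm = 1,
      conf_low = 0, conf_high = 0, flag = "constant"))
  }
  structure(list(coefficients = coefs, variant = variant,
                 n_perm = n_perm, seed = seed, epsilon = epsilon,
                 n_dyads = nrow(dyads), n_individuals = n_ind,
                 response_metric = attr(dyads, "metric") %||% "jaccard_index",
                 window_minutes = attr(dyads, "window_minutes"),
                 network_kind = attr(dyads, "network_kind")),
            class = "dyadic_fit")
}

#' Dyadic regression of microbiota similarity on social association
#'
#' Fits, on the logit scale, microbiota similarity against social
#' association strength plus the spatial-distance, sampling-interval,
#' kinship, sex-similarity and age-similarity covariates.  Inference is by
#' node-label permutation: individual identities are permuted jointly across
#' every individual-level pairwise structure (social, spatial, kinship, sex,
#' age) while the response and the sample-level sampling interval stay
#' fixed, preserving the dyadic and repeat-sample dependence; the model is
#' refit per permutation.  Two-sided p-values use +1 smoothing; 95%
#' intervals come from the 2.5/97.5 percentiles of
#' \eqn{\hat\beta - (\beta^* - \bar\beta^*)}.
#'
#' @param dyads a [build_dyad_table()] tibble.
#' @param n_perm number of node-label permutations (>= 99).
#' @param seed integer seed.
#' @param epsilon logit clamp for the proportion response.
#' @return A `"dyadic_fit"` object; see [tidy.dyadic_fit()] and
#'   [glance.dyadic_fit()].  Covariates with zero variance are reported with
#'   estimate 0, p 1 and flag `"constant"`.
#' @export
fit_dyadic_model <- function(dyads, n_perm = 999, seed = 1, epsilon = 1e-6) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  dyadic_perm_engine(
    dyads,
    covariate_cols = c("social_strength", "spatial_distance", "kinship",
                       "sex_same", "age_same"),
    fixed_cols = "sampling_interval",
    n_perm = n_perm, seed = seed, epsilon = epsilon, variant = "main")
}

#' Sex-interaction dyadic model
#'
#' As [fit_dyadic_model()], but social association strength enters with a
#' separate slope per dyad sex category (FF, MF, MM) alongside category main
#' effects, so sex-dependent transmission shows up as category-specific
#' social slopes.  Categories with fewer than two dyads are flagged
#' inestimable and receive no slope.
#'
#' @inheritParams fit_dyadic_model
#' @return A `"dyadic_fit"` object (variant `"sex_interaction"`) whose terms
#'   include `social_FF`, `social_MF`, `social_MM` for the categories
#'   present.
#' @export
fit_sex_interaction <- function(dyads, n_perm = 999, seed = 1,
                                epsilon = 1e-6) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  ids <- sort(unique(c(dyads$id_a, dyads$id_b)))
  male <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  first <- dyads[!duplicated(paste(dyads$id_a, dyads$id_b)), ]
  n_male_dyad <- match(first$dyad_sex_category, c("FF", "MF", "MM")) - 1
  male[cbind(first$id_a, first$id_b)] <- n_male_dyad
  male[cbind(first$id_b, first$id_a)] <- n_male_dyad
  soc <- dyad_covariate_matrix(dyads, "social_strength", ids)

  tab <- table(first$dyad_sex_category)
  usable <- names(tab)[tab >= 2]
  dropped <- setdiff(names(tab), usable)
  if (length(dropped)) {
    inform(sprintf("Sex categor(ies) with < 2 dyads flagged inestimable: %s",
                   paste(dropped, collapse = ", ")))
  }
  cats <- c("FF", "MF", "MM")
  builder <- function(pia, pib) {
    nm <- male[cbind(pia, pib)]
    sc <- soc[cbind(pia, pib)]
    X <- NULL
    # category main effects (baseline = first usable category)
    for (cat in usable[-1]) {
      X <- cbind(X, as.numeric(nm == match(cat, cats) - 1))
      colnames(X)[ncol(X)] <- paste0("category_", cat)
    }
    for (cat in usable) {
      X <- cbind(X, sc * (nm == match(cat, cats) - 1))
      colnames(X)[ncol(X)] <- paste0("social_", cat)
    }
    X
  }
  fit <- dyadic_perm_engine(
    dyads,
    covariate_cols = c("spatial_distance", "kinship", "age_same"),
    fixed_cols = "sampling_interval",
    n_perm = n_perm, seed = seed, epsilon = epsilon,
    variant = "sex_interaction",
    extra = list(builder = builder))
  if (length(dropped)) {
    fit$coefficients <- bind_rows(
      fit$coefficients,
      tibble(term = paste0("social_", dropped), estimate = NA_real_,
             p_perm = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
             flag = "inestimable"))
  }
  fit
}

#' Multiple Regression Quadratic Assignment Procedure (MRQAP)
#'
#' Dyadic matrix regression with Double-Semi-Partialing inference: the
#' response's upper triangle is regressed on the predictors'; for each
#' predictor, its matrix is residualised on the remaining predictors, the
#' residual matrix's rows and columns are permuted jointly `n_perm` times,
#' the model is refit and the permutation p-value is the (+1-smoothed)
#' proportion of |t| statistics at least as large as observed.
#'
#' @param response square symmetric numeric matrix.
#' @param predictors named list of square symmetric matrices, same order and
#'   dimension as `response`.
#' @param n_perm number of matrix permutations.
#' @param seed integer seed.
#' @return A `"mrqap_fit"` object with a coefficient tibble (`term`,
#'   `estimate`, `t`, `p_perm`).
#' @export
mrqap <- function(response, predictors, n_perm = 999, seed = 1) {
  stopifnot_square_symmetric(response, "response")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    abort("`predictors` must be a named list.")
  }
  purrr::iwalk(predictors, function(m, nm) {
    stopifnot_square_symmetric(m, nm)
    if (!all(dim(m) == dim(response))) {
      abort(sprintf("Predictor '%s' does not match the response dimension.", nm))
    }
  })
  n <- nrow(response)
  y <- upper_tri_vec(response)
  Xp <- vapply(predictors, upper_tri_vec, numeric(length(y)))
  X <- cbind(`(intercept)` = 1, Xp)
  full <- ols_fit(X, y)
  terms <- names(predictors)

  p_perm <- withr::with_seed(seed, {
    vapply(seq_along(terms), function(k) {
      others <- X[, -(k + 1), drop = FALSE]
      e_fit <- ols_fit(others, Xp[, k])
      E <- matrix(0, n, n)
      E[upper.tri(E)] <- e_fit$residuals
      E <- E + t(E)
      t_obs <- full$t[k + 1]
      t_star <- vapply(seq_len(n_perm), function(b) {
        pi_b <- sample.int(n)
        Eb <- E[pi_b, pi_b]
        Xb <- cbind(others, upper_tri_vec(Eb))
        ols_fit(Xb, y)$t[ncol(Xb)]
      }, numeric(1))
      perm_pvalue(t_obs, t_star)
    }, numeric(1))
  })
  structure(list(
    coefficients = tibble(term = c("(intercept)", terms),
                          estimate = full$beta, t = full$t,
                          p_perm = c(NA_real_, p_perm)),
    n_perm = n_perm, seed = seed, n_nodes = n, variant = "mrqap"),
    class = "mrqap_fit")
}

#' MRQAP check of the social-microbiota association
#'
#' Builds an individual-level response by selecting one random sample per
#' individual (seeded), logit-transforming the between-individual similarity
#' of the selected samples, and regressing it on the social network,
#' spatial-distance and kinship matrices with [mrqap()].  The draw is
#' repeated `n_draws` times and the median permutation p-value and mean
#' estimate per term are reported, so the result does not hinge on one
#' arbitrary sample selection.
#'
#' @param similarity sample-level `"similarity_matrix"`.
#' @param sri `"assoc_matrix"` of social association strength.
#' @param spatial a [spatial_summary()] or individual distance matrix.
#' @param kinship kinship matrix.
#' @param samples sample metadata.
#' @param n_perm,seed permutation settings.
#' @param n_draws number of repeated one-sample-per-individual draws.
#' @param epsilon logit clamp.
#' @return A tibble per term: `term`, `estimate` (mean over draws), `p_perm`
#'   (median over draws), with draw-level results in attribute `"draws"`.
#' @export
mrqap_microbiota <- function(similarity, sri, spatial, kinship, samples,
                             n_perm = 999, seed = 1, n_draws = 10,
                             epsilon = 1e-6) {
  dmat <- if (inherits(spatial, "spatial_summary")) spatial$distance else spatial
  metric <- attr(similarity, "metric") %||% "jaccard_index"
  sim <- unclass(similarity)
  if (metric == "bray_curtis_dissimilarity") sim <- 1 - sim
  ids <- intersect(intersect(rownames(sri), rownames(dmat)),
                   intersect(rownames(kinship), unique(samples$individual_id)))
  samples <- samples[samples$individual_id %in% ids &
                       samples$sample_id %in% rownames(sim), , drop = FALSE]
  draws <- purrr::map(seq_len(n_draws), function(d) {
    chosen <- withr::with_seed(seed + d, {
      samples |> group_by(.data$individual_id) |>
        dplyr::slice_sample(n = 1) |> ungroup()
    })
    sel_ids <- chosen$individual_id
    resp <- logit_clamp(sim[chosen$sample_id, chosen$sample_id], epsilon)
    diag(resp) <- 0
    dimnames(resp) <- list(sel_ids, sel_ids)
    fit <- mrqap(resp,
                 list(social = sri[sel_ids, sel_ids],
                      spatial = dmat[sel_ids, sel_ids],
                      kinship = kinship[sel_ids, sel_ids]),
                 n_perm = n_perm, seed = seed + d)
    mutate(fit$coefficients, draw = d)
  }) |> bind_rows()
  out <- draws |>
    filter(.data$term != "(intercept)") |>
    group_by(.data$term) |>
    summarise(estimate = mean(.data$estimate),
              p_perm = median(.data$p_perm), .groups = "drop")
  attr(out, "draws") <- draws
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Collapse a sample-level similarity matrix to individuals
#'
#' Mean similarity over all between-individual sample pairs per dyad.
#'
#' @param similarity sample-level `"similarity_matrix"`.
#' @param samples sample metadata.
#' @return Individual-by-individual symmetric matrix (diagonal 1 for
#'   similarity metrics, 0 for dissimilarity).
#' @export
individual_similarity <- function(similarity, samples) {
  sim <- unclass(similarity)
  samples <- samples[samples$sample_id %in% rownames(sim), , drop = FALSE]
  ids <- sort(unique(samples$individual_id))
  out <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  by_ind <- split(samples$sample_id, samples$individual_id)
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1)) {
      block <- sim[by_ind[[ids[a]]], by_ind[[ids[b]]], drop = FALSE]
      out[a, b] <- out[b, a] <- mean(block)
    }
  }
  diag(out) <- if (identical(attr(similarity, "metric"),
                             "bray_curtis_dissimilarity")) 0 else 1
  out
}

#' Mantel test of kinship against microbiota similarity
#'
#' @param similarity_ind individual-level similarity matrix
#'   ([individual_similarity()]).
#' @param kinship kinship matrix over (a superset of) the same individuals.
#' @param n_perm,seed permutation settings.
#' @return A tibble with `r`, `p`, `n_individuals`, `n_perm`, `seed`.
#' @export
mantel_kinship <- function(similarity_ind, kinship, n_perm = 999, seed = 1) {
  ids <- intersect(rownames(similarity_ind), rownames(kinship))
  if (length(ids) < 3) abort("Too few shared individuals for a Mantel test.")
  fit <- withr::with_seed(seed, vegan::mantel(
    as.dist(similarity_ind[ids, ids]), as.dist(kinship[ids, ids]),
    permutations = n_perm))
  tibble(r = unname(fit$statistic), p = unname(fit$signif),
         n_individuals = length(ids), n_perm = n_perm, seed = seed)
}

#' PERMANOVA on microbiota composition
#'
#' Partitions squared compositional distances among sample-level factors
#' (vegan's `adonis2`), with marginal (each term given all others) or
#' sequential testing and permutation p-values.
#'
#' @param similarity sample-level `"similarity_matrix"`; Jaccard similarities
#'   are converted to distances (1 - similarity), Bray-Curtis
#'   dissimilarities are used directly.
#' @param factors data frame of factors, one row per sample, rownames (or a
#'   `sample_id` column) matching the similarity matrix.
#' @param n_perm,seed permutation settings.
#' @param mode `"marginal"` or `"sequential"`.
#' @param strata optional factor restricting permutations within its levels.
#' @return A tibble: `term`, `df`, `sum_of_squares`, `R2`, `pseudo_F`, `p`.
#' @export
permanova <- function(similarity, factors, n_perm = 999, seed = 1,
                      mode = c("marginal", "sequential"), strata = NULL) {
  mode <- match.arg(mode)
  if ("sample_id" %in% names(factors)) {
    factors <- as.data.frame(factors)
    rownames(factors) <- factors$sample_id
    factors$sample_id <- NULL
  }
  sim <- unclass(similarity)
  ids <- intersect(rownames(sim), rownames(factors))
  factors <- factors[ids, , drop = FALSE]
  for (nm in names(factors)) {
    if (length(unique(factors[[nm]])) < 2) {
      abort(sprintf("Factor '%s' has a single level.", nm))
    }
  }
  d <- if (identical(attr(similarity, "metric"),
                     "bray_curtis_dissimilarity")) {
    as.dist(sim[ids, ids])
  } else {
    as.dist(1 - sim[ids, ids])
  }
  perm <- if (is.null(strata)) n_perm else
    permute::how(nperm = n_perm, blocks = factors[[strata]])
  rhs <- paste(setdiff(names(factors), strata), collapse = " + ")
  fml <- stats::as.formula(paste("d ~", rhs))
  fit <- withr::with_seed(seed, vegan::adonis2(
    fml, data = factors, permutations = perm,
    by = if (mode == "marginal") "margin" else "terms"))
  tibble(term = rownames(fit), df = fit$Df, sum_of_squares = fit$SumOfSqs,
         R2 = fit$R2, pseudo_F = fit$F, p = fit$`Pr(>F)`)
}
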