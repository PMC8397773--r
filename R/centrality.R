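#' Six node-centrality metrics of a weighted association network
#'
#' For each individual: degree (count of nonzero edges), weighted degree
#' (strength, sum of SRI weights), eigenvector centrality (principal
#' eigenvector of the weight matrix, scaled to max 1), betweenness on
#' weighted shortest paths with edge distances 1/weight (unnormalised),
#' information centrality in the Stephenson-Zelen resistance formulation
#' (edge weights as conductances; equal to n divided by the node's total
#' resistance distance to all others, computed per connected component), and
#' bridge propensity: the mean over a node's partners of one minus their
#' neighbourhood overlap, where
#' overlap(i, j) = |N(i) inter N(j)| / |N(i) union N(j) minus \{i, j\}|
#' (a documented convention for "connecting different parts of the
#' network"; empty unions count as overlap 0).
#'
#' @param m an `"assoc_matrix"` of nonnegative weights.
#' @return A tibble with one row per individual: `individual_id`, `degree`,
#'   `weighted_degree`, `eigenvector`, `betweenness`, `information`,
#'   `bridge`, `component`, `in_largest_component`.  Isolated nodes get
#'   information centrality 0 and bridge `NA`.
#' @export
centrality_suite <- function(m) {
  w <- unclass(m)
  stopifnot_square_symmetric(w, "association matrix")
  ids <- rownames(w) %||% as.character(seq_len(nrow(w)))
  n <- nrow(w)
  adj <- w > 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  largest <- which.max(comp$csize)

  degree <- rowSums(adj)
  wdeg <- rowSums(w)
  eig <- if (any(w > 0)) {
    igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  } else rep(0, n)
  btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                             normalized = FALSE)

  info <- numeric(n)
  for (k in seq_len(comp$no)) {
    memb <- which(comp$membership == k)
    if (length(memb) == 1) { info[memb] <- 0; next }
    info[memb] <- information_centrality(w[memb, memb, drop = FALSE])
  }

  bridge <- vapply(seq_len(n), function(i) {
    partners <- which(adj[i, ])
    if (!length(partners)) return(NA_real_)
    mean(vapply(partners, function(j) {
      ni <- which(adj[i, ]); nj <- which(adj[j, ])
      un <- setdiff(union(ni, nj), c(i, j))
      ov <- if (!length(un)) 0 else length(intersect(ni, nj)) / length(un)
      1 - ov
    }, numeric(1)))
  }, numeric(1))

  tibble(individual_id = ids, degree = as.numeric(degree),
         weighted_degree = as.numeric(wdeg),
         eigenvector = as.numeric(eig), betweenness = as.numeric(btw),
         information = info, bridge = bridge,
         component = as.integer(comp$membership),
         in_largest_component = comp$membership == largest)
}

# Stephenson-Zelen information centrality of one connected component.
# With L the weighted Laplacian and C = (L + J)^{-1} (J all-ones),
# I_i = 1 / (C_ii + (tr C - 2 sum_j C_ij)/n), equal to n over the node's
# summed resistance distances.
information_centrality <- function(w) {
  n <- nrow(w)
  L <- diag(rowSums(w)) - w
  C <- solve(L + matrix(1, n, n))
  tr <- sum(diag(C))
  rs <- rowSums(C)
  1 / (diag(C) + (tr - 2 * rs) / n)
}

#' Screen sample-level covariates of microbiota diversity
#'
#' Fits the covariate-only linear model of a diversity response and retains
#' terms whose type-II F-test p-value is below the threshold, mirroring a
#' two-stage simplify-then-test workflow.
#'
#' @param data data frame holding the response and candidate covariates.
#' @param response response column name (e.g. `"richness_asymptotic"`).
#' @param covariates character vector of candidate covariate columns.
#' @param threshold retention p-value threshold (default 0.1).
#' @return A list: `retained` (character vector) and `screen` (tibble of
#'   term-level p-values).
#' @export
covariate_screen <- function(data, response, covariates, threshold = 0.1) {
  if (!length(covariates)) {
    return(list(retained = character(),
                screen = tibble(term = character(), p = numeric())))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = data)
  dr <- stats::drop1(fit, test = "F")
  tab <- tibble(term = rownames(dr)[-1], p = dr$`Pr(>F)`[-1])
  list(retained = tab$term[!is.na(tab$p) & tab$p < threshold], screen = tab)
}

#' Does a centrality metric predict microbiota diversity?
#'
#' Aggregates the diversity response to one value per individual (mean over
#' its samples), fits a linear model of diversity on the retained covariates
#' plus a single centrality metric, and tests the centrality slope two ways:
#' `p_model` from the regression fit and `p_perm` from node permutations in
#' which the centrality values are shuffled across individuals and the model
#' refit.  Following a two-stage rule, `p_perm` is computed only when
#' `p_model` < 0.05 (force it with `always_permute = TRUE`).
#'
#' @param centrality a [centrality_suite()] tibble.
#' @param diversity an [alpha_diversity()] tibble.
#' @param samples sample metadata mapping samples to individuals.
#' @param metric_name centrality column to test (e.g. `"degree"`).
#' @param response `"richness"` (asymptotic richness, default) or
#'   `"shannon"` (asymptotic Shannon).
#' @param covariates optional data frame of per-individual covariates with
#'   an `individual_id` column.
#' @param n_perm number of node permutations (default 1000).
#' @param seed integer seed.
#' @param always_permute compute `p_perm` regardless of `p_model`.
#' @return A one-row tibble of class `"diversity_model_result"`: `metric`,
#'   `response`, `estimate`, `p_model`, `p_perm`, `n_individuals`,
#'   `n_perm`, `seed`, `covariates`.
#' @export
diversity_model <- function(centrality, diversity, samples, metric_name,
                            response = c("richness", "shannon"),
                            covariates = NULL, n_perm = 1000, seed = 1,
                            always_permute = FALSE) {
  response <- match.arg(response)
  resp_col <- if (response == "richness") "richness_asymptotic" else
    "shannon_asymptotic"
  ind <- diversity |>
    inner_join(samples[, c("sample_id", "individual_id")], by = "sample_id") |>
    group_by(.data$individual_id) |>
    summarise(div = mean(.data[[resp_col]]), .groups = "drop") |>
    inner_join(centrality[, c("individual_id", metric_name)],
               by = "individual_id")
  covar_names <- character()
  if (!is.null(covariates)) {
    ind <- inner_join(ind, covariates, by = "individual_id")
    covar_names <- setdiff(names(covariates), "individual_id")
  }
  cent <- ind[[metric_name]]
  if (var(cent) == 0) {
    abort(sprintf("Centrality metric '%s' is constant; inestimable.",
                  metric_name))
  }
  Xc <- if (length(covar_names)) {
    stats::model.matrix(stats::as.formula(
      paste("~", paste(covar_names, collapse = " + "))), data = ind)
  } else matrix(1, nrow(ind), 1)
  X <- cbind(Xc, metric = cent)
  fit <- ols_fit(X, ind$div)
  k <- ncol(X)
  est <- fit$beta[k]
  p_model <- 2 * stats::pt(abs(fit$t[k]), df = fit$df, lower.tail = FALSE)
  p_perm <- NA_real_
  if (always_permute || (!is.na(p_model) && p_model < 0.05)) {
    perm_est <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
      Xb <- X
      Xb[, k] <- cent[sample.int(length(cent))]
      ols_beta(Xb, ind$div)[k]
    }, numeric(1)))
    p_perm <- perm_pvalue(est, perm_est)
  }
  structure(tibble(metric = metric_name, response = response,
                   estimate = est, p_model = p_model, p_perm = p_perm,
                   n_individuals = nrow(ind), n_perm = n_perm, seed = seed,
                   covariates = paste(covar_names, collapse = ",")),
            class = c("diversity_model_result", class(tibble())))
}
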