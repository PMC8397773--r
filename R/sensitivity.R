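#' Thin a network to a target edge count
#'
#' Retains the `target_edge_count` highest-weight edges of the network,
#' setting all other entries to zero; retained weights are unchanged (no
#' renormalisation).  Ties at the cutoff weight are broken by a seeded
#' uniform draw so the result is reproducible.
#'
#' @param m an `"assoc_matrix"`.
#' @param target_edge_count number of edges to keep (at most the current
#'   edge count).
#' @param seed integer seed for tie-breaking.
#' @return A thinned `"assoc_matrix"` with attribute `thinned = TRUE`.
#' @export
thin_network <- function(m, target_edge_count, seed = 1) {
  w <- unclass(m)
  prs <- pair_index(nrow(w))
  wt <- w[prs]
  nz <- which(wt > 0)
  if (target_edge_count > length(nz)) {
    abort(sprintf("Target edge count %d exceeds the %d available edges.",
                  target_edge_count, length(nz)))
  }
  keep <- withr::with_seed(seed, {
    ord <- order(wt[nz], runif(length(nz)), decreasing = TRUE)
    nz[ord[seq_len(target_edge_count)]]
  })
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  out[prs[keep, , drop = FALSE]] <- wt[keep]
  out[prs[keep, c(2, 1), drop = FALSE]] <- wt[keep]
  res <- assoc_matrix(out, attr(m, "kind") %||% "SRI",
                      attr(m, "window_minutes"))
  attr(res, "thinned") <- TRUE
  res
}

#' Density-matched edge-thinning null analysis
#'
#' For each target network, thins the reference (least intimate, 12 h)
#' network to the same edge count by removing its weakest edges, rebuilds
#' the dyad table with the thinned network as the social predictor, refits
#' the dyadic model, and pairs the thinned-network social-effect estimate
#' with the real network's.  A social-effect gradient across edge
#' definitions that vanishes in the thinned nulls cannot be explained by
#' network density alone.
#'
#' @param m12 the reference `"assoc_matrix"` (12 h window).
#' @param real_networks named list of real `"assoc_matrix"` objects, one per
#'   window.
#' @param build_dyads function taking an association matrix and returning a
#'   [build_dyad_table()] tibble.
#' @param n_perm,seed permutation settings passed to [fit_dyadic_model()].
#' @return A tibble of class `"thinning_result"`: per window the real and
#'   thinned social-effect estimates, their permutation p-values and both
#'   edge counts.
#' @export
thinning_null_analysis <- function(m12, real_networks, build_dyads,
                                   n_perm = 999, seed = 1) {
  rows <- purrr::imap(real_networks, function(mw, label) {
    ec <- sum(upper_tri_vec(unclass(mw)) > 0)
    thin <- thin_network(m12, ec, seed = seed)
    fit_real <- fit_dyadic_model(build_dyads(mw), n_perm = n_perm,
                                 seed = seed)
    fit_thin <- fit_dyadic_model(build_dyads(thin), n_perm = n_perm,
                                 seed = seed)
    real_soc <- filter(fit_real$coefficients,
                       .data$term == "social_strength")
    thin_soc <- filter(fit_thin$coefficients,
                       .data$term == "social_strength")
    tibble(window = label,
           window_minutes = attr(mw, "window_minutes") %||% NA_real_,
           n_edges_real = ec,
           n_edges_thinned = sum(upper_tri_vec(unclass(thin)) > 0),
           estimate_real = real_soc$estimate, p_real = real_soc$p_perm,
           estimate_thinned = thin_soc$estimate, p_thinned = thin_soc$p_perm,
           n_perm = n_perm, seed = seed)
  })
  structure(bind_rows(rows),
            class = c("thinning_result", class(tibble())))
}

#' Leave-one-bacterial-family-out dropout analysis
#'
#' For each bacterial family in the filtered taxonomy (ASVs without a family
#' assignment are pooled as `"Unassigned"`), removes the family's ASVs,
#' recomputes the Jaccard similarity, rebuilds the dyad table for each
#' requested network and refits the dyadic model.  Families whose strong
#' attenuation of the social effect identifies candidate socially
#' transmitted taxa.  The same permutation seed is reused for every family
#' so differences reflect composition, not Monte-Carlo noise.
#'
#' @param ct a filtered `community_table`.
#' @param networks named list of `"assoc_matrix"` objects (e.g. the 12 h and
#'   2 min networks).
#' @param spatial,kinship,individuals,samples inputs passed to
#'   [build_dyad_table()].
#' @param n_perm,seed permutation settings.
#' @return A tibble of class `"dropout_result"`: per family and network the
#'   family's ASV richness (and its log), the social-effect estimate, 95%
#'   interval and permutation p-value with that family excluded.  Families
#'   whose removal empties any sample's support are flagged and the affected
#'   samples dropped.
#' @export
family_dropout <- function(ct, networks, spatial, kinship, individuals,
                           samples, n_perm = 999, seed = 1) {
  fam <- ct$taxonomy$Family
  fam[is.na(fam) | fam == ""] <- "Unassigned"
  families <- sort(unique(fam))
  rows <- purrr::map(families, function(f) {
    keep_asv <- fam != f
    sub <- community_table(ct$counts[, keep_asv, drop = FALSE],
                           ct$taxonomy[keep_asv, , drop = FALSE],
                           state = "raw")
    empty <- rowSums(sub$counts) == 0
    flag <- NA_character_
    if (any(empty)) {
      inform(sprintf(
        "Family %s: removal empties %d sample(s); dropping them.",
        f, sum(empty)))
      sub$counts <- sub$counts[!empty, , drop = FALSE]
      flag <- "empties_samples"
    }
    sim <- jaccard_similarity(sub)
    purrr::imap(networks, function(mw, label) {
      dy <- build_dyad_table(sim, mw, spatial, kinship, individuals,
                             samples)
      fit <- fit_dyadic_model(dy, n_perm = n_perm, seed = seed)
      soc <- filter(fit$coefficients, .data$term == "social_strength")
      tibble(family = f, network = label,
             window_minutes = attr(mw, "window_minutes") %||% NA_real_,
             n_asvs_family = sum(!keep_asv),
             log_richness = log(max(sum(!keep_asv), 1)),
             estimate = soc$estimate, conf_low = soc$conf_low,
             conf_high = soc$conf_high, p_perm = soc$p_perm,
             n_dyads = fit$n_dyads, flag = flag,
             n_perm = n_perm, seed = seed)
    }) |> bind_rows()
  })
  structure(bind_rows(rows),
            class = c("dropout_result", class(tibble())))
}
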