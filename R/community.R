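#' Construct a community table
#'
#' Couples a samples-by-ASVs count matrix with its taxonomy and a processing
#' state flag.  All microbiota operations consume and return this container.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns,
#'   non-negative; integer counts unless `state` is `"normalised"`.
#' @param taxonomy tibble with column `asv_id` plus taxonomic ranks
#'   (`Kingdom`, `Phylum`, `Class`, `Order`, `Family`); must cover every ASV
#'   column.
#' @param state one of `"raw"`, `"filtered"`, `"normalised"`, `"rarefied"`.
#' @return An object of class `"community_table"`: a list with elements
#'   `counts`, `taxonomy`, `state`.
#' @export
community_table <- function(counts, taxonomy,
                            state = c("raw", "filtered", "normalised",
                                      "rarefied")) {
  state <- match.arg(state)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs sample ids as rownames and ASV ids as colnames.")
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  uncovered <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(uncovered)) {
    abort(sprintf("ASV(s) missing from the taxonomy: %s",
                  paste(uncovered, collapse = ", ")))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id), , drop = FALSE]
  structure(list(counts = counts, taxonomy = as_tibble(taxonomy),
                 state = state),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table: %d samples x %d ASVs, state '%s'>\n",
              nrow(x$counts), ncol(x$counts), x$state))
  invisible(x)
}

#' Remove singleton and non-gut ASVs
#'
#' Drops ASVs whose total count across the whole table is one (the
#' DADA2-downstream singleton convention; a per-sample alternative is
#' available) and ASVs assigned to non-gut taxa, by default Cyanobacteria and
#' Mitochondria, matched against any taxonomic rank.
#'
#' @param ct a raw [community_table()].
#' @param singleton `"total"` (default): an ASV is a singleton when its
#'   summed count over all samples equals 1; `"per_sample"`: counts of 1 are
#'   zeroed per cell and ASVs left empty are dropped.
#' @param exclude_taxa character vector of taxon names to remove wherever
#'   they appear in the taxonomy.
#' @return A filtered `community_table` (state `"filtered"`).
#' @export
filter_community <- function(ct, singleton = c("total", "per_sample"),
                             exclude_taxa = c("Cyanobacteria", "Mitochondria")) {
  singleton <- match.arg(singleton)
  counts <- ct$counts
  tax <- ct$taxonomy
  rank_cols <- setdiff(names(tax), "asv_id")
  in_excluded <- apply(as.matrix(tax[rank_cols]), 1,
                       function(r) any(r %in% exclude_taxa))
  is_zero <- colSums(counts) == 0
  if (singleton == "per_sample") {
    counts[counts == 1] <- 0
    is_singleton <- colSums(counts) == 0 & !is_zero
  } else {
    is_singleton <- colSums(counts) == 1
  }
  drop <- in_excluded | is_singleton | is_zero
  inform(sprintf(
    "Filtered %d ASV(s): %d singleton(s), %d in excluded taxa, %d unobserved; %d ASV(s) retained.",
    sum(drop), sum(is_singleton), sum(in_excluded), sum(is_zero), sum(!drop)))
  if (all(drop)) abort("Filtering removed every ASV.")
  community_table(counts[, !drop, drop = FALSE],
                  tax[!drop, , drop = FALSE], state = "filtered")
}

#' Normalise counts to proportional abundance within each sample
#'
#' @param ct a filtered [community_table()] with no all-zero sample.
#' @return A `community_table` whose rows sum to one (state `"normalised"`).
#' @export
normalise_community <- function(ct) {
  totals <- rowSums(ct$counts)
  if (any(totals == 0)) {
    abort(sprintf("All-zero sample(s): %s",
                  paste(rownames(ct$counts)[totals == 0], collapse = ", ")))
  }
  out <- community_table(ct$counts / totals, ct$taxonomy, state = "raw")
  out$state <- "normalised"
  out
}

#' Rarefy a community table to even depth
#'
#' Subsamples reads without replacement to a common depth per sample
#' (via [vegan::rrarefy()]); samples below the depth are dropped with a
#' message.  Deterministic under `seed`.
#'
#' @param ct a `community_table` with integer counts.
#' @param depth target reads per sample; default 90% of the minimum retained
#'   sample sum.
#' @param seed integer seed.
#' @return A rarefied `community_table`.
#' @export
rarefy_community <- function(ct, depth = NULL, seed = 1) {
  if (ct$state == "normalised") abort("Rarefaction needs integer counts.")
  totals <- rowSums(ct$counts)
  depth <- depth %||% floor(0.9 * min(totals))
  if (depth <= 0) abort("`depth` must be positive.")
  keep <- totals >= depth
  if (any(!keep)) {
    inform(sprintf("Dropped %d sample(s) below depth %d: %s",
                   sum(!keep), depth,
                   paste(rownames(ct$counts)[!keep], collapse = ", ")))
  }
  counts <- ct$counts[keep, , drop = FALSE]
  rare <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      # advisory about count magnitudes on toy tables; counts are validated
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- community_table(rare, ct$taxonomy, state = "raw")
  out$state <- "rarefied"
  out
}

similarity_matrix <- function(m, metric) {
  stopifnot_square_symmetric(m, "similarity")
  structure(m, metric = metric, class = c("similarity_matrix", class(m)))
}

#' Jaccard Index between samples
#'
#' The proportion of ASVs shared between two samples,
#' \eqn{|A \cap B| / |A \cup B|} over presence sets (1 minus the binary
#' Jaccard distance).  Presence is strictly positive abundance, so the index
#' is identical on raw filtered counts and on proportions.
#'
#' @param ct a `community_table`.
#' @return A sample-by-sample `"similarity_matrix"` (diagonal 1, metric
#'   `"jaccard_index"`).  Pairs in which either sample has empty support get
#'   value 0 and are listed in the `"empty_pairs"` attribute.
#' @export
jaccard_similarity <- function(ct) {
  pa <- (ct$counts > 0) * 1
  empty <- rowSums(pa) == 0
  d <- as.matrix(vegan::vegdist(pa, method = "jaccard", binary = TRUE))
  s <- 1 - d
  if (any(empty)) {
    s[empty, ] <- 0
    s[, empty] <- 0
  }
  diag(s) <- 1
  out <- similarity_matrix(s, "jaccard_index")
  attr(out, "empty_pairs") <- rownames(pa)[empty]
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' Abundance-weighted dissimilarity
#' \eqn{1 - 2\sum_i \min(p_{si}, p_{ti}) / (\sum_i p_{si} + \sum_i p_{ti})}
#' on proportional abundances.
#'
#' @param ct a normalised `community_table`.
#' @return A sample-by-sample `"similarity_matrix"` holding dissimilarities
#'   (diagonal 0, metric `"bray_curtis_dissimilarity"`).
#' @export
bray_curtis <- function(ct) {
  if (ct$state != "normalised") {
    abort("Bray-Curtis expects a normalised community table.")
  }
  empty <- rowSums(ct$counts) == 0
  d <- as.matrix(vegan::vegdist(ct$counts, method = "bray"))
  if (any(empty)) {
    d[empty, ] <- 1
    d[, empty] <- 1
  }
  diag(d) <- 0
  out <- similarity_matrix(d, "bray_curtis_dissimilarity")
  attr(out, "empty_pairs") <- rownames(ct$counts)[empty]
  out
}

#' Observed and asymptotic alpha diversity per sample
#'
#' Computes, from integer counts, the observed ASV richness, singleton and
#' doubleton counts, the Chao1 asymptotic richness
#' (\eqn{S_{obs} + f_1^2/(2 f_2)} when \eqn{f_2 > 0}, else
#' \eqn{S_{obs} + f_1 (f_1 - 1)/2}), the observed Shannon entropy and the
#' Chao-Jost asymptotic Shannon entropy (coverage-based bias correction for
#' unseen taxa).
#'
#' @param ct a `community_table` with integer counts (pre-normalisation).
#' @param low_coverage_reads samples with fewer reads are flagged
#'   `low_coverage` (still computed).
#' @return A tibble with one row per sample: `sample_id`, `reads`,
#'   `richness_obs`, `f1`, `f2`, `richness_asymptotic`, `shannon_obs`,
#'   `shannon_asymptotic`, `low_coverage`.
#' @export
alpha_diversity <- function(ct, low_coverage_reads = 10) {
  if (ct$state == "normalised") abort("Alpha diversity needs integer counts.")
  rows <- purrr::map(rownames(ct$counts), function(s) {
    x <- ct$counts[s, ]
    x <- x[x > 0]
    n <- sum(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    s_obs <- length(x)
    chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    p <- x / n
    sh_obs <- -sum(p * log(p))
    tibble(sample_id = s, reads = n, richness_obs = s_obs, f1 = f1, f2 = f2,
           richness_asymptotic = chao1, shannon_obs = sh_obs,
           shannon_asymptotic = chao_jost_shannon(x),
           low_coverage = n < low_coverage_reads)
  })
  bind_rows(rows)
}

# Chao-Jost asymptotic Shannon entropy from a vector of positive counts.
# First term uses the identity
#   sum_{k=1}^{n-1} (1/k) C(n-x, k)/C(n-1, k) = sum_{k=x}^{n-1} 1/k
#                                             = digamma(n) - digamma(x),
# the unseen-species correction follows the f1/f2 coverage estimator.
chao_jost_shannon <- function(x) {
  n <- sum(x)
  if (n <= 1) return(0)
  h <- sum(x / n * (digamma(n) - digamma(x)))
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(h)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else 2 / ((n - 1) * (f1 - 1) + 2)
  if (A < 1) {
    r <- seq_len(n - 1)
    h <- h + f1 / n * (1 - A)^(1 - n) *
      (-log(A) - sum((1 - A)^r / r))
  }
  h
}
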