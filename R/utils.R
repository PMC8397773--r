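#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n across all_of rename distinct pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats qlogis plogis rnorm runif rpois rbinom rmultinom rlnorm
#'   setNames dist lm coef quantile cor sd var median as.dist anova
#' @importFrom utils combn head
NULL

# clamp then logit; epsilon keeps 0/1 similarities finite on the logit scale
logit_clamp <- function(p, epsilon = 1e-6) {
  stats::qlogis(pmin(pmax(p, epsilon), 1 - epsilon))
}

#' Extract the upper triangle of a square matrix as a vector
#' @param m square matrix
#' @return numeric vector, column-major upper triangle (no diagonal)
#' @keywords internal
#' @noRd
upper_tri_vec <- function(m) m[upper.tri(m)]

# all unordered pairs of 1..n as a two-column integer matrix (i < j)
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

# build a symmetric matrix from dyad rows (ids + value); missing dyads -> fill
dyads_to_matrix <- function(id_a, id_b, value, ids, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(id_a, ids), match(id_b, ids))] <- value
  m[cbind(match(id_b, ids), match(id_a, ids))] <- value
  diag(m) <- 0
  m
}

stopifnot_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  invisible(m)
}

# ordinary least squares with t statistics; X must include the intercept
ols_fit <- function(X, y) {
  XtX_inv <- solve(crossprod(X))
  beta <- as.numeric(XtX_inv %*% crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / max(df, 1)
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  list(beta = beta, se = se, t = beta / se, df = df, residuals = as.numeric(res))
}

# fast coefficient-only refit used inside permutation loops
ols_beta <- function(X, y) stats::.lm.fit(X, y)$coefficients

perm_pvalue <- function(obs, perm) {
  # two-sided permutation p with +1 smoothing
  (1 + sum(abs(perm) >= abs(obs), na.rm = TRUE)) / (sum(!is.na(perm)) + 1)
}

perm_interval <- function(obs, perm, level = 0.95) {
  # basic (shift-corrected) permutation interval around the observed estimate
  centred <- perm - mean(perm, na.rm = TRUE)
  a <- (1 - level) / 2
  qs <- stats::quantile(centred, c(1 - a, a), na.rm = TRUE, names = FALSE)
  c(obs - qs[1], obs - qs[2])
}
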