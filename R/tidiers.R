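#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dyadic permutation fit
#'
#' @param x a `"dyadic_fit"` object.
#' @param ... unused.
#' @return The coefficient tibble: `term`, `estimate` (logit scale),
#'   `p_perm`, `conf_low`, `conf_high`, `flag`.
#' @method tidy dyadic_fit
#' @export
tidy.dyadic_fit <- function(x, ...) x$coefficients

#' One-row summary of a dyadic permutation fit
#'
#' @param x a `"dyadic_fit"` object.
#' @param ... unused.
#' @return A one-row tibble with the model variant, sizes and provenance
#'   (window, permutation count, seed, response metric).
#' @method glance dyadic_fit
#' @export
glance.dyadic_fit <- function(x, ...) {
  tibble(variant = x$variant, n_dyads = x$n_dyads,
         n_individuals = x$n_individuals, n_perm = x$n_perm, seed = x$seed,
         response_metric = x$response_metric,
         window_minutes = x$window_minutes %||% NA_real_,
         network_kind = x$network_kind %||% NA_character_)
}

#' @export
print.dyadic_fit <- function(x, ...) {
  cat(sprintf(
    "<dyadic_fit '%s': %d dyads, %d individuals, %d permutations, seed %d>\n",
    x$variant, x$n_dyads, x$n_individuals, x$n_perm, x$seed))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy mrqap_fit
#' @export
tidy.mrqap_fit <- function(x, ...) x$coefficients

#' @method glance mrqap_fit
#' @export
glance.mrqap_fit <- function(x, ...) {
  tibble(variant = x$variant, n_nodes = x$n_nodes, n_perm = x$n_perm,
         seed = x$seed)
}

#' @export
print.mrqap_fit <- function(x, ...) {
  cat(sprintf("<mrqap_fit: %d nodes, %d permutations, seed %d>\n",
              x$n_nodes, x$n_perm, x$seed))
  print(x$coefficients)
  invisible(x)
}

#' Coefficient plot of a dyadic fit
#'
#' Estimates with their permutation 95% intervals, one point per model term;
#' terms whose interval excludes zero predict microbiota similarity.
#'
#' @param object a `"dyadic_fit"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dyadic_fit
#' @export
autoplot.dyadic_fit <- function(object, ...) {
  df <- filter(object$coefficients, is.na(.data$flag))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Effect on logit microbiota similarity", y = NULL,
                  title = sprintf("Dyadic model (%s)", object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot a thinning-null analysis
#'
#' Real-network social-effect estimates against the density-matched
#' thinned-reference estimates across edge definitions.
#'
#' @param object a `"thinning_result"` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot thinning_result
#' @export
autoplot.thinning_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("estimate_real", "estimate_thinned"),
                            names_to = "network", names_prefix = "estimate_",
                            values_to = "estimate")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$window_minutes),
                                   y = .data$estimate,
                                   colour = .data$network,
                                   group = .data$network)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "Association window (minutes)",
                  y = "Social effect (logit scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a family-dropout analysis
#'
#' Social-effect estimates (with permutation intervals) after excluding each
#' bacterial family, against the family's log ASV richness.
#'
#' @param object a `"dropout_result"` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dropout_result
#' @export
autoplot.dropout_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate,
                                       y = .data$log_richness)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$network) +
    ggplot2::labs(x = "Social effect with family excluded (logit scale)",
                  y = "log ASV richness of excluded family") +
    ggplot2::theme_minimal()
}

#' Heatmap of an association matrix
#'
#' @param object an `"assoc_matrix"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot assoc_matrix
#' @export
autoplot.assoc_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(unclass(object),
                                      responseName = "weight"))
  names(df)[1:2] <- c("id_a", "id_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = attr(object, "kind") %||% "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
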