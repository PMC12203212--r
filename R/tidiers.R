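# broom-style tidiers and plotting for the tabular result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a core gene set
#'
#' One row per selected core cluster with its coverages.
#' @param x a `core_gene_set`
#' @param ... unused
#' @return tibble (cluster_id, n_members, single_copy_coverage,
#'   any_copy_coverage)
#' @method tidy core_gene_set
#' @export
tidy.core_gene_set <- function(x, ...) {
  x$core[, c("cluster_id", "n_members", "single_copy_coverage",
             "any_copy_coverage")]
}

#' @rdname tidy.core_gene_set
#' @return `glance`: one-row tibble (n_core, threshold, min_coverage,
#'   median_coverage)
#' @method glance core_gene_set
#' @export
glance.core_gene_set <- function(x, ...) {
  tibble::tibble(
    n_core = nrow(x$core),
    threshold = x$threshold,
    min_coverage = if (nrow(x$core)) min(x$core$single_copy_coverage)
                   else NA_real_,
    median_coverage = if (nrow(x$core))
      stats::median(x$core$single_copy_coverage) else NA_real_)
}

#' Plot the single-copy coverage spectrum of a clustering
#'
#' Histogram of per-cluster single-copy coverage with the core-gene
#' threshold marked; the mass at the right of the line is the core set.
#' @param object a `core_gene_set` (plots all profiles when `profiles` is
#'   supplied, otherwise the selected core clusters only)
#' @param profiles optional full [profile_clusters()] tibble
#' @param ... unused
#' @return a ggplot
#' @method autoplot core_gene_set
#' @export
autoplot.core_gene_set <- function(object, profiles = NULL, ...) {
  tb <- if (!is.null(profiles)) profiles else object$core
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$single_copy_coverage)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "single-copy coverage", y = "clusters",
                  title = sprintf("core genes: %d clusters at threshold %.2f",
                                  nrow(object$core), object$threshold)) +
    ggplot2::theme_minimal()
}
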