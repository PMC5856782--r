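# broom-style tidiers for the package's fitted-object classes.

#' Tidy a genotype PCA
#'
#' @param x An `altipop_pca`.
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @method tidy altipop_pca
#' @export
tidy.altipop_pca <- function(x, ...) x$scores

#' @rdname tidy.altipop_pca
#' @return For `glance()`, one row per component with variance-explained
#'   fractions.
#' @method glance altipop_pca
#' @export
glance.altipop_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained,
         n_sites = x$n_sites)
}

#' Tidy an ABC posterior
#'
#' @param x An `altipop_abc`.
#' @param ... Unused.
#' @return Accepted parameter draws with distances.
#' @method tidy altipop_abc
#' @export
tidy.altipop_abc <- function(x, ...) x$accepted

#' @rdname tidy.altipop_abc
#' @return For `glance()`, the per-parameter posterior summary (mean,
#'   median, central 95% interval).
#' @method glance altipop_abc
#' @export
glance.altipop_abc <- function(x, ...) x$summary

#' Tidy a random-effects meta-analysis
#'
#' @param x An `altipop_meta`.
#' @param ... Unused.
#' @return Per-study effects and normalized weights.
#' @method tidy altipop_meta
#' @export
tidy.altipop_meta <- function(x, ...) x$weights

#' @rdname tidy.altipop_meta
#' @return For `glance()`, the one-row pooled summary.
#' @method glance altipop_meta
#' @export
glance.altipop_meta <- function(x, ...) {
  tibble(pooled = x$pooled, se = x$se, tau2 = x$tau2,
         ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         z = x$z, p_value = x$p_value, q = x$q, k = x$k)
}
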