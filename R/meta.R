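#' Hedges' g effect size
#'
#' Small-sample bias-corrected standardized mean difference:
#' `d = (mean1 - mean2)/s_pooled`, `J = 1 - 3/(4*(n1+n2-2) - 1)`, `g = J*d`,
#' `var_g = J^2 * ((n1+n2)/(n1*n2) + d^2/(2*(n1+n2-2)))`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (vectorised).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Tibble: `g`, `var_g`.
#' @examples
#' hedges_g(1, 1, 10, 0, 1, 10)
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  assert_that(all(n1 >= 2) && all(n2 >= 2), "group sizes must be >= 2")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  assert_that(all(sp > 0), "zero pooled sd: standardization undefined")
  d <- (mean1 - mean2) / sp
  J <- 1 - 3 / (4 * df - 1)
  tibble(g = J * d,
         var_g = J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * df)))
}

#' Compute study effects from raw summaries
#'
#' @param studies Tibble with `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`
#'   (and optionally `study`, `moderator`), e.g. from
#'   [simulate_meta_studies()] or [contrast_studies()].
#' @param drop_degenerate Drop (with a warning) studies whose pooled sd is
#'   zero — possible when resampled pseudo-studies draw identical values —
#'   instead of erroring (default TRUE).
#' @return The input with `g` and `var_g` columns appended.
#' @export
study_effects <- function(studies, drop_degenerate = TRUE) {
  sp2 <- ((studies$n1 - 1) * studies$sd1^2 + (studies$n2 - 1) * studies$sd2^2) /
    (studies$n1 + studies$n2 - 2)
  if (drop_degenerate && any(sp2 <= 0)) {
    warning(sum(sp2 <= 0), " study(ies) with zero pooled sd dropped",
            call. = FALSE)
    studies <- studies[sp2 > 0, , drop = FALSE]
  }
  eff <- hedges_g(studies$mean1, studies$sd1, studies$n1,
                  studies$mean2, studies$sd2, studies$n2)
  dplyr::bind_cols(studies, eff)
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Method-of-moments between-study variance:
#' fixed-effect weights `w = 1/var_g`, `Q = sum(w*(g - g_FE)^2)`,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effects
#' weights `1/(var_g + tau2)` give the pooled effect, its SE, z, two-sided
#' normal p and 95% CI.
#'
#' @param effects Tibble with `g` and `var_g` (see [study_effects()]).
#' @return Object of class `altipop_meta` (list with `pooled`, `se`, `tau2`,
#'   `ci_lo`, `ci_hi`, `z`, `p_value`, `q`, `df`, `k`, and a per-study
#'   `weights` tibble with normalized weights).
#' @export
pool_random_effects <- function(effects) {
  assert_that(all(effects$var_g > 0), "var_g must be positive")
  k <- nrow(effects)
  g <- effects$g
  v <- effects$var_g
  if (k == 1) {
    out <- list(pooled = g, se = sqrt(v), tau2 = NA_real_,
                ci_lo = g - 1.959964 * sqrt(v), ci_hi = g + 1.959964 * sqrt(v),
                z = g / sqrt(v), p_value = 2 * pnorm(-abs(g / sqrt(v))),
                q = NA_real_, df = 0L, k = 1L,
                weights = tibble(study = if ("study" %in% names(effects)) effects$study else "S1",
                                 weight = 1))
    return(structure(out, class = "altipop_meta"))
  }
  w <- 1 / v
  g_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - g_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  pooled <- sum(wr * g) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- pooled / se
  out <- list(pooled = pooled, se = se, tau2 = tau2,
              ci_lo = pooled - 1.959964 * se, ci_hi = pooled + 1.959964 * se,
              z = z, p_value = 2 * pnorm(-abs(z)),
              q = q, df = k - 1L, k = k,
              weights = tibble(
                study = if ("study" %in% names(effects)) effects$study else
                  paste0("S", seq_len(k)),
                g = g, var_g = v, weight = wr / sum(wr)))
  structure(out, class = "altipop_meta")
}

#' @export
print.altipop_meta <- function(x, ...) {
  cat(sprintf("<altipop_meta> pooled g = %.4f (SE %.4f), tau2 = %s, k = %d\n",
              x$pooled, x$se,
              ifelse(is.na(x$tau2), "NA", sprintf("%.4f", x$tau2)), x$k))
  cat(sprintf("  95%% CI [%.4f, %.4f], z = %.3f, p = %.4g\n",
              x$ci_lo, x$ci_hi, x$z, x$p_value))
  invisible(x)
}

#' Random-effects meta-regression on a moderator
#'
#' Weighted least squares of study effects on a numeric moderator with
#' weights `1/(var_g + tau2)`, `tau2` taken from the intercept-only
#' DerSimonian-Laird fit (method of moments), and normal-theory inference
#' from `solve(t(X) W X)`.
#'
#' @param effects Tibble with `g`, `var_g`.
#' @param moderator Numeric covariate, one value per study, non-constant.
#' @return Tibble: `term` (intercept, moderator), `estimate`, `se`, `z`,
#'   `p_value`; attribute `tau2`.
#' @export
meta_regression <- function(effects, moderator) {
  k <- nrow(effects)
  assert_that(k >= 3, "meta-regression needs >= 3 studies")
  assert_that(length(moderator) == k, "one moderator value per study")
  assert_that(sd(moderator) > 0, "moderator must be non-constant")
  tau2 <- pool_random_effects(effects)$tau2
  w <- 1 / (effects$var_g + tau2)
  X <- cbind(intercept = 1, moderator = moderator)
  xtw <- t(X * w)
  V <- solve(xtw %*% X)
  beta <- drop(V %*% (xtw %*% effects$g))
  se <- sqrt(diag(V))
  z <- beta / se
  out <- tibble(term = c("intercept", "moderator"),
                estimate = unname(beta), se = unname(se), z = unname(z),
                p_value = 2 * pnorm(-abs(unname(z))))
  attr(out, "tau2") <- tau2
  out
}

#' Randomize per-sample measurements into pseudo-studies
#'
#' For each site (population), forms `per_set` pseudo-studies by seeded
#' resampling of that site's per-sample measurement values — with
#' replacement by default, or as a without-replacement partition when the
#' site has at least `per_set * size` values. Each pseudo-study is
#' summarised as (mean, sd, n), ready for Hedges' g contrasts against a
#' reference site.
#'
#' @param values Numeric measurements (e.g. per-sample SNP densities).
#' @param site Site/population label per value.
#' @param per_set Pseudo-studies per site (default 9, i.e. 27 studies for
#'   three sites).
#' @param size Values resampled per pseudo-study (default: the site's own
#'   sample count).
#' @param mode `"resample"` (with replacement, default) or `"partition"`
#'   (without replacement).
#' @param seed Optional seed; a fixed seed gives an identical partition.
#' @return Tibble: `study`, `site`, `mean`, `sd`, `n`.
#' @export
randomize_studies <- function(values, site, per_set = 9, size = NULL,
                              mode = c("resample", "partition"), seed = NULL) {
  mode <- match.arg(mode)
  assert_that(length(values) == length(site), "values and site must align")
  assert_that(length(values) > 0, "empty site: no measurements given")
  groups <- split(values, site)
  assert_that(all(lengths(groups) > 0), "empty site")
  with_seed_if(seed, {
    rows <- lapply(names(groups), function(s) {
      v <- groups[[s]]
      m <- size %||% length(v)
      assert_that(m >= 2, "pseudo-studies need >= 2 values (sd undefined)")
      draws <- if (mode == "resample") {
        lapply(seq_len(per_set), function(i) sample(v, m, replace = TRUE))
      } else {
        assert_that(length(v) >= per_set * m,
                    "not enough values for a without-replacement partition")
        idx <- sample(seq_along(v))
        lapply(seq_len(per_set), function(i) v[idx[((i - 1) * m + 1):(i * m)]])
      }
      tibble(study = paste0(s, "_", seq_len(per_set)), site = s,
             mean = vapply(draws, mean, numeric(1)),
             sd = vapply(draws, sd, numeric(1)),
             n = m)
    })
    dplyr::bind_rows(rows)
  })
}

#' Pair pseudo-studies of two sites into effect-size studies
#'
#' Pairs the i-th pseudo-study of the target site with the i-th of the
#' reference site, yielding raw two-group summaries for [study_effects()].
#'
#' @param studies Output of [randomize_studies()].
#' @param target,reference Site labels; `g > 0` means the target site's
#'   measurements exceed the reference's.
#' @param moderator Optional single numeric (e.g. target altitude) stored
#'   per paired study.
#' @return Tibble: `study`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`
#'   (1 = target, 2 = reference), optional `moderator`.
#' @export
contrast_studies <- function(studies, target, reference, moderator = NULL) {
  t1 <- studies[studies$site == target, ]
  t2 <- studies[studies$site == reference, ]
  assert_that(nrow(t1) > 0 && nrow(t2) > 0, "unknown target or reference site")
  k <- min(nrow(t1), nrow(t2))
  out <- tibble(study = paste0(target, "_vs_", reference, "_", seq_len(k)),
                mean1 = t1$mean[seq_len(k)], sd1 = t1$sd[seq_len(k)],
                n1 = t1$n[seq_len(k)],
                mean2 = t2$mean[seq_len(k)], sd2 = t2$sd[seq_len(k)],
                n2 = t2$n[seq_len(k)])
  if (!is.null(moderator)) out$moderator <- moderator
  out
}
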