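#' Generative model of per-transcript SNP density
#'
#' The model expresses per-transcript SNP counts through three components:
#' a per-bp SNP rate `mu` for each population, a saturating read-occurrence
#' (detection) factor `c = E / (E + kappa)` driven by expression level `E`,
#' and multiplicative lognormal expression fluctuation with sd `sigma_rpkm`.
#' Counts are `Poisson(mu_pop * length * c)`; the summary statistics are the
#' mean and sd over transcripts of the per-transcript density
#' (`count / length`, scaled to SNPs/Mb), per population.
#'
#' @param mu Named per-population per-bp SNP rates (> 0).
#' @param kappa Detection saturation constant (> 0); as `kappa -> 0` every
#'   expressed transcript is fully detected.
#' @param sigma_rpkm Lognormal sd of expression fluctuation (>= 0).
#' @param transcripts Tibble `length` (bp) and `expression` (arbitrary RPKM
#'   scale), one row per transcript.
#' @param seed Optional seed.
#' @return Tibble: `population`, `mean_density`, `sd_density` (SNPs/Mb).
#' @export
simulate_density_model <- function(mu, kappa, sigma_rpkm, transcripts, seed = NULL) {
  assert_that(all(mu > 0), "mu must be positive")
  assert_that(kappa > 0, "kappa must be positive")
  assert_that(sigma_rpkm >= 0, "sigma_rpkm must be non-negative")
  assert_that(nrow(transcripts) > 0, "transcripts must be non-empty")
  L <- transcripts$length
  E0 <- transcripts$expression
  with_seed_if(seed, {
    rows <- lapply(names(mu), function(p) {
      E <- E0 * rlnorm(length(E0), 0, sigma_rpkm)
      cfac <- E / (E + kappa)
      cnt <- rpois(length(L), mu[[p]] * L * cfac)
      dens <- cnt / L * 1e6
      tibble(population = p, mean_density = mean(dens), sd_density = sd(dens))
    })
    dplyr::bind_rows(rows)
  })
}

#' Configuration for rejection ABC on SNP density
#'
#' @param priors Named list of length-2 `c(lo, hi)` uniform prior ranges for
#'   `mu_<pop>` (one per population), `kappa`, `sigma_rpkm`.
#' @param n_sims Number of prior draws (>= 100).
#' @param tolerance_quantile Fraction of closest simulations accepted,
#'   in (0, 1].
#' @param seed Integer seed.
#' @return List of class `abc_config`.
#' @export
abc_config <- function(priors, n_sims = 20000, tolerance_quantile = 0.01,
                       seed = 1L) {
  assert_that(n_sims >= 100, "n_sims must be >= 100")
  assert_that(tolerance_quantile > 0 && tolerance_quantile <= 1,
              "tolerance_quantile must lie in (0, 1]")
  ok <- vapply(priors, function(r) length(r) == 2 && r[1] <= r[2], logical(1))
  assert_that(all(ok), "each prior must be c(lo, hi) with lo <= hi")
  structure(list(priors = priors, n_sims = as.integer(n_sims),
                 tolerance_quantile = tolerance_quantile,
                 seed = as.integer(seed)),
            class = "abc_config")
}

# Simulate summary statistics for a matrix of parameter draws (rows = sims),
# fully vectorised across simulations.
abc_simulate_pool <- function(params, transcripts, pops) {
  n_sims <- nrow(params)
  L <- transcripts$length
  E0 <- transcripts$expression
  tn <- length(L)
  out <- matrix(NA_real_, n_sims, 2 * length(pops))
  colnames(out) <- as.vector(rbind(paste0("mean_", pops), paste0("sd_", pops)))
  for (p in pops) {
    noise <- matrix(rlnorm(tn * n_sims, 0, rep(params[, "sigma_rpkm"], each = tn)),
                    nrow = tn)
    E <- E0 * noise
    cfac <- E / sweep(E, 2, params[, "kappa"], "+")
    lam <- (L * cfac) * rep(params[, paste0("mu_", p)], each = tn)
    dens <- matrix(rpois(tn * n_sims, lam), nrow = tn) / L * 1e6
    mu_hat <- colMeans(dens)
    sd_hat <- sqrt(colSums(sweep(dens, 2, mu_hat)^2) / (tn - 1))
    out[, paste0("mean_", p)] <- mu_hat
    out[, paste0("sd_", p)] <- sd_hat
  }
  out
}

#' Rejection ABC for the SNP-density model
#'
#' Draws `n_sims` parameter vectors from independent uniform priors,
#' simulates the density model for each, and accepts the
#' `tolerance_quantile` fraction closest to the observed summaries under a
#' Euclidean distance with each summary standardized by its
#' across-simulation sd (summaries with zero pool sd are dropped with a
#' warning).
#'
#' @param observed Tibble as returned by [simulate_density_model()] (or by
#'   [observed_density_summaries()]), or a named numeric vector of
#'   summaries.
#' @param config An [abc_config()].
#' @param transcripts Tibble `length`, `expression`.
#' @return Object of class `altipop_abc`: `accepted` (tibble of parameter
#'   draws + `distance`), `summary` (per-parameter mean/median/central 95%),
#'   `max_accepted_distance`, `min_rejected_distance`, `config`.
#' @export
abc_rejection <- function(observed, config, transcripts) {
  stopifnot(inherits(config, "abc_config"))
  if (is.data.frame(observed)) {
    obs <- c(setNames(observed$mean_density, paste0("mean_", observed$population)),
             setNames(observed$sd_density, paste0("sd_", observed$population)))
  } else {
    obs <- observed
  }
  assert_that(all(is.finite(obs)), "observed summaries must be finite")
  par_names <- names(config$priors)
  pops <- sub("^mu_", "", grep("^mu_", par_names, value = TRUE))

  with_seed_if(config$seed, {
    params <- vapply(config$priors,
                     function(r) runif(config$n_sims, r[1], r[2]),
                     numeric(config$n_sims))
    colnames(params) <- par_names
    sims <- abc_simulate_pool(params, transcripts, pops)
    sims <- sims[, names(obs), drop = FALSE]

    sds <- apply(sims, 2, sd)
    use <- sds > 0
    if (!all(use)) {
      warning("summary statistic(s) with zero simulation sd dropped: ",
              paste(names(obs)[!use], collapse = ", "), call. = FALSE)
    }
    z <- sweep(sims[, use, drop = FALSE], 2, sds[use], "/")
    zo <- obs[use] / sds[use]
    distance <- sqrt(rowSums(sweep(z, 2, zo)^2))

    k <- max(1L, round(config$n_sims * config$tolerance_quantile))
    ord <- order(distance)
    acc <- ord[seq_len(k)]
    accepted <- as_tibble(as.data.frame(params[acc, , drop = FALSE]))
    accepted$distance <- distance[acc]

    smry <- purrr::map_dfr(par_names, function(nm) {
      v <- accepted[[nm]]
      tibble(parameter = nm, mean = mean(v), median = median(v),
             q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975)))
    })
    structure(list(accepted = accepted,
                   summary = smry,
                   observed = obs,
                   max_accepted_distance = max(distance[acc]),
                   min_rejected_distance = if (k < config$n_sims)
                     min(distance[ord[(k + 1):config$n_sims]]) else NA_real_,
                   config = config),
              class = "altipop_abc")
  })
}

#' @export
print.altipop_abc <- function(x, ...) {
  cat("<altipop_abc>", nrow(x$accepted), "accepted of", x$config$n_sims,
      "simulations (tolerance", x$config$tolerance_quantile, ")\n")
  print(x$summary)
  invisible(x)
}

#' Observed per-transcript density summaries from a variant table
#'
#' Computes, per population, the mean and sd over transcripts of the
#' per-transcript segregating-SNP density (sites carrying at least one alt
#' allele in the population, per covered Mb) — the observed side of the ABC
#' comparison.
#'
#' @param variants A variant table.
#' @param design A [pop_design()].
#' @param annotation Transcript annotation.
#' @return Tibble: `population`, `mean_density`, `sd_density`.
#' @export
observed_density_summaries <- function(variants, design, annotation) {
  counts <- pop_allele_counts(variants, design)
  pops <- pop_levels(design)
  rows <- lapply(pops, function(p) {
    present <- counts$alt[, p] > 0
    per_tr <- tibble(unit = variants$transcript_id, present = present) |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(n = sum(.data$present), .groups = "drop")
    per_tr <- dplyr::left_join(tibble(unit = annotation$transcript_id,
                                      L = annotation$covered_bp),
                               per_tr, by = "unit")
    per_tr$n[is.na(per_tr$n)] <- 0
    dens <- per_tr$n / per_tr$L * 1e6
    tibble(population = p, mean_density = mean(dens), sd_density = sd(dens))
  })
  dplyr::bind_rows(rows)
}

#' Posterior bifurcation test for the high-altitude SNP rate
#'
#' Posterior probability that the highest population's SNP rate exceeds
#' `ratio_threshold` times the mean of the other two populations' rates,
#' with a decision flag at a configurable posterior-probability cutoff.
#'
#' @param posterior An `altipop_abc`.
#' @param ratio_threshold Rate-ratio threshold (default 1.5).
#' @param prob_cutoff Posterior probability needed to flag (default 0.95).
#' @param high,low Parameter names: the focal rate and the baseline rates.
#' @return Tibble: `posterior_prob`, `ratio_threshold`, `flag`.
#' @export
bifurcation_test <- function(posterior, ratio_threshold = 1.5,
                             prob_cutoff = 0.95,
                             high = "mu_H", low = c("mu_L", "mu_M")) {
  acc <- posterior$accepted
  assert_that(nrow(acc) > 0, "posterior is empty")
  base <- rowMeans(as.matrix(acc[, low, drop = FALSE]))
  prob <- mean(acc[[high]] > ratio_threshold * base)
  tibble(posterior_prob = prob, ratio_threshold = ratio_threshold,
         flag = prob > prob_cutoff)
}
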