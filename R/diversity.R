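#' Watterson's theta
#'
#' Per-site Watterson estimate `theta = S / (a1 * L)` with
#' `a1 = sum(1/i, i = 1..n-1)` the harmonic number of the sample size.
#'
#' @param S Number of segregating sites (vectorised).
#' @param n Number of sampled chromosomes (>= 2).
#' @param L Covered length in bp (> 0).
#' @return Per-site theta.
#' @examples
#' watterson_theta(1, 2, 1) # a1 = 1, theta = 1
#' @export
watterson_theta <- function(S, n, L) {
  assert_that(all(n >= 2), "theta undefined for n < 2")
  assert_that(all(L > 0), "L must be positive")
  a1 <- vapply(n, function(k) sum(1 / seq_len(k - 1)), numeric(1))
  S / (a1 * L)
}

# Unbiased per-site heterozygosity 2*p*(1-p)*n/(n-1) from alt-allele count
# and called chromosomes; equals the mean pairwise difference at the site.
site_heterozygosity <- function(alt, called) {
  h <- rep(NA_real_, length(alt))
  ok <- called >= 2
  h[ok] <- 2 * alt[ok] * (called[ok] - alt[ok]) / (called[ok] * (called[ok] - 1))
  h
}

#' Nucleotide diversity from genotype dosages
#'
#' Per-site pi as the average over sites of the unbiased heterozygosity
#' `2*p*(1-p)*n/(n-1)` with `p` the sample alt-allele frequency; this equals
#' the mean pairwise difference per site between sampled chromosomes.
#' Sites with missing calls use their own called-chromosome count; sites with
#' fewer than two called chromosomes are skipped (count reported in attribute
#' `n_skipped`).
#'
#' @param alt Per-site alt-allele counts.
#' @param called Per-site called chromosome counts.
#' @param L Covered length in bp.
#' @return Per-site pi, with attribute `k` (pi summed over sites, the mean
#'   pairwise difference count used by Tajima's D) and `n_skipped`.
#' @export
nucleotide_diversity <- function(alt, called, L) {
  assert_that(L > 0, "L must be positive")
  h <- site_heterozygosity(alt, called)
  n_skipped <- sum(is.na(h))
  k <- sum(h, na.rm = TRUE)
  structure(k / L, k = k, n_skipped = n_skipped)
}

# Tajima (1989) constant cascade for sample size n (chromosomes).
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` with `k` the mean pairwise
#' difference count (pi summed over sites, not per site) and the constants of
#' Tajima (1989). Undefined (returns `NA`) when `S = 0`.
#'
#' @param S Segregating sites.
#' @param k Mean pairwise differences summed over the unit's sites.
#' @param n Sampled chromosomes (>= 2; >= 4 recommended for stability).
#' @return Tajima's D, `NA` when undefined.
#' @export
tajimas_d <- function(S, k, n) {
  assert_that(all(n >= 2), "Tajima's D needs n >= 2")
  if (S == 0) return(NA_real_)
  cc <- tajima_constants(n)
  (k - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Per-gene and genome-wide diversity statistics
#'
#' For each unit (gene, or the pooled genome) and each population: the number
#' of segregating sites S, sampled chromosomes n, covered length L, per-site
#' Watterson theta, per-site pi and Tajima's D. Per-gene pi values aggregate
#' to the genome-wide value under length weighting.
#'
#' @param variants A variant table.
#' @param design A [pop_design()] (>= 2 samples per population).
#' @param annotation Transcript annotation with `covered_bp`.
#' @param by `"gene"` for per-transcript rows, `"genome"` for one pooled row
#'   per population.
#' @return Tibble: `unit_id`, `population`, `S`, `n`, `L`, `theta_w`, `pi`,
#'   `tajima_d`.
#' @export
diversity_stats <- function(variants, design, annotation, by = c("gene", "genome")) {
  by <- match.arg(by)
  check_design_covers(design, variants, min_per_pop = 2)
  counts <- pop_allele_counts(variants, design)
  pops <- pop_levels(design)
  pop_n <- vapply(pops, function(p) 2L * sum(design$population == p), integer(1))

  unit_of <- if (by == "gene") variants$transcript_id else rep("genome", nrow(variants))
  units <- if (by == "gene") annotation$transcript_id else "genome"
  unit_L <- if (by == "gene") {
    setNames(annotation$covered_bp, annotation$transcript_id)
  } else {
    c(genome = sum(annotation$covered_bp))
  }

  rows <- lapply(pops, function(p) {
    a <- counts$alt[, p]; nc <- counts$called[, p]
    seg <- a > 0 & a < nc
    h <- site_heterozygosity(a, nc)
    df <- tibble(unit = unit_of, seg = seg, h = h) |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(S = sum(.data$seg, na.rm = TRUE),
                       k = sum(.data$h, na.rm = TRUE), .groups = "drop")
    df <- dplyr::left_join(tibble(unit = units), df, by = "unit")
    df$S[is.na(df$S)] <- 0L
    df$k[is.na(df$k)] <- 0
    L <- unname(unit_L[df$unit])
    n_chr <- pop_n[[p]]
    tibble(unit_id = df$unit, population = p,
           S = as.integer(df$S), n = n_chr, L = L,
           theta_w = watterson_theta(df$S, n_chr, L),
           pi = df$k / L,
           tajima_d = vapply(seq_len(nrow(df)),
                             function(i) tajimas_d(df$S[i], df$k[i], n_chr),
                             numeric(1)))
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$unit_id, factor(.data$population, levels = pops))
}

#' Proportions of Tajima's D beyond thresholds
#'
#' Proportion of defined D values above `upper` and below `lower`; undefined
#' values (S = 0 units) are excluded from the denominator and reported.
#'
#' @param d Vector of Tajima's D values (`NA` = undefined).
#' @param upper,lower Thresholds (defaults 1.5 and -1).
#' @return Tibble: `prop_above`, `prop_below`, `n_defined`, `n_undefined`.
#' @export
d_threshold_bins <- function(d, upper = 1.5, lower = -1) {
  defined <- d[!is.na(d)]
  assert_that(length(defined) >= 1, "no defined D values")
  tibble(prop_above = mean(defined > upper),
         prop_below = mean(defined < lower),
         n_defined = length(defined),
         n_undefined = sum(is.na(d)))
}

#' Two-sample pooled t-test (equal variances)
#'
#' Classical equal-variance two-sample t with a two-sided p-value on
#' `n_a + n_b - 2` degrees of freedom. Degenerate inputs follow the
#' convention: zero pooled variance with equal means gives p = 1, with
#' unequal means p = 0.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return Tibble: `estimate` (mean difference a - b), `t`, `df`, `p_value`.
#' @export
pooled_t_test <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    return(tibble(estimate = diff, t = ifelse(diff == 0, 0, Inf * sign(diff)),
                  df = df, p_value = ifelse(diff == 0, 1, 0)))
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  tibble(estimate = diff, t = t, df = df, p_value = 2 * pt(-abs(t), df))
}
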