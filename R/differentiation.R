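#' Hudson's FST (ratio of averages)
#'
#' Per-site numerator `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `D = p1(1-p2) + p2(1-p1)`; the multi-site estimate is
#' `sum(N)/sum(D)` over sites with `D > 0` (sites monomorphic for the same
#' allele in both populations are excluded). The raw ratio may be negative;
#' it is clamped to [0, 1] with the raw value kept as attribute `raw`.
#'
#' @param p1,p2 Per-site alt-allele sample frequencies.
#' @param n1,n2 Per-site called chromosome counts (>= 2).
#' @param clamp Clamp the aggregate into [0, 1] (default TRUE).
#' @return FST estimate (`NA` if every site is excluded), with attributes
#'   `raw` and `n_sites` (sites used).
#' @export
hudson_fst <- function(p1, p2, n1, n2, clamp = TRUE) {
  assert_that(all(n1 >= 2) && all(n2 >= 2), "need >= 2 chromosomes per site")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- den > 0
  if (!any(use)) return(structure(NA_real_, raw = NA_real_, n_sites = 0L))
  raw <- sum(num[use]) / sum(den[use])
  val <- if (clamp) min(max(raw, 0), 1) else raw
  structure(val, raw = raw, n_sites = sum(use))
}

#' Nei's GST
#'
#' `H_S` is the mean over populations of within-population expected
#' heterozygosity `2*p*(1-p)`, `H_T = 2*pbar*(1-pbar)` with `pbar` the mean
#' frequency; `GST = 1 - sum(H_S)/sum(H_T)` across sites with `H_T > 0`.
#'
#' @param p Sites-by-populations matrix of alt-allele frequencies.
#' @return GST in [0, 1] (`NA` if `H_T = 0` at every site), attribute
#'   `n_sites`.
#' @export
nei_gst <- function(p) {
  p <- as.matrix(p)
  assert_that(ncol(p) >= 2, "need >= 2 populations")
  hs <- rowMeans(2 * p * (1 - p))
  pbar <- rowMeans(p)
  ht <- 2 * pbar * (1 - pbar)
  use <- ht > 0
  if (!any(use)) return(structure(NA_real_, n_sites = 0L))
  structure(1 - sum(hs[use]) / sum(ht[use]), n_sites = sum(use))
}

# Weir & Cockerham (1984) theta for two populations at biallelic sites,
# from per-site frequencies, sample sizes (individuals) and observed
# heterozygote frequencies. Ratio-of-sums aggregation.
wc_fst <- function(p1, p2, n1, n2, h1, h2, clamp = TRUE) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  use <- tot != 0 & is.finite(tot)
  if (!any(use)) return(structure(NA_real_, raw = NA_real_, n_sites = 0L))
  raw <- sum(a[use]) / sum(tot[use])
  val <- if (clamp) min(max(raw, 0), 1) else raw
  structure(val, raw = raw, n_sites = sum(use))
}

#' Per-gene (or genome-wide) differentiation statistics
#'
#' Pairwise FST for every population pair plus Nei's GST over all
#' populations, per gene or pooled. Per-gene estimates use only sites with at
#' least one called genotype in every population of the comparison.
#'
#' @param variants A variant table.
#' @param design A [pop_design()].
#' @param by `"gene"` or `"genome"`.
#' @param estimator `"hudson"` (default) or `"wc"` (Weir-Cockerham 1984) for
#'   the pairwise statistic.
#' @return Tibble: `unit_id`, `n_sites`, `fst_<A>_<B>` (clamped) and
#'   `fst_raw_<A>_<B>` per pair, `gst`.
#' @export
differentiation_stats <- function(variants, design, by = c("gene", "genome"),
                                  estimator = c("hudson", "wc")) {
  by <- match.arg(by)
  estimator <- match.arg(estimator)
  check_design_covers(design, variants, min_per_pop = 2)
  counts <- pop_allele_counts(variants, design)
  pops <- pop_levels(design)
  freq <- counts$alt / pmax(counts$called, 1)

  het <- NULL
  n_ind <- NULL
  if (estimator == "wc") {
    het <- n_ind <- matrix(0, nrow(variants), length(pops),
                           dimnames = list(NULL, pops))
    for (p in pops) {
      cols <- design$sample[design$population == p]
      sub <- as.matrix(variants[, cols, drop = FALSE])
      n_ind[, p] <- rowSums(!is.na(sub))
      het[, p] <- rowSums(sub == 1L, na.rm = TRUE) / pmax(n_ind[, p], 1)
    }
  }

  unit_of <- if (by == "gene") variants$transcript_id else rep("genome", nrow(variants))
  idx_by_unit <- split(seq_len(nrow(variants)), unit_of)
  pairs <- utils::combn(pops, 2, simplify = FALSE)

  one_unit <- function(idx) {
    ok <- rowSums(counts$called[idx, , drop = FALSE] >= 2) == length(pops)
    idx <- idx[ok]
    row <- list(n_sites = length(idx))
    for (pr in pairs) {
      nm <- paste(pr, collapse = "_")
      if (length(idx) == 0) {
        row[[paste0("fst_", nm)]] <- NA_real_
        row[[paste0("fst_raw_", nm)]] <- NA_real_
        next
      }
      est <- if (estimator == "hudson") {
        hudson_fst(freq[idx, pr[1]], freq[idx, pr[2]],
                   counts$called[idx, pr[1]], counts$called[idx, pr[2]])
      } else {
        wc_fst(freq[idx, pr[1]], freq[idx, pr[2]],
               n_ind[idx, pr[1]], n_ind[idx, pr[2]],
               het[idx, pr[1]], het[idx, pr[2]])
      }
      row[[paste0("fst_", nm)]] <- as.numeric(est)
      row[[paste0("fst_raw_", nm)]] <- attr(est, "raw")
    }
    row$gst <- if (length(idx) == 0) NA_real_ else
      as.numeric(nei_gst(freq[idx, , drop = FALSE]))
    tibble::as_tibble(row)
  }

  out <- dplyr::bind_rows(lapply(idx_by_unit, one_unit))
  out <- dplyr::bind_cols(tibble(unit_id = names(idx_by_unit)), out)
  dplyr::arrange(out, .data$unit_id)
}

#' Locus-specific branch lengths from three pairwise distances
#'
#' Decomposes pairwise distances of three populations A, B, C into
#' per-population branch lengths: `lsbl_A = (d_AB + d_AC - d_BC) / 2` and
#' cyclically. Negative inputs are clamped to 0 before decomposition;
#' negative branch lengths are reported as 0 with the raw value kept.
#' The decomposition is exactly invertible: `d_AB = lsbl_A + lsbl_B` (on the
#' raw values).
#'
#' @param d_ab,d_ac,d_bc Pairwise distances (vectorised; e.g. per-gene FST).
#' @return Tibble: `lsbl_a`, `lsbl_b`, `lsbl_c` (clamped at 0) and
#'   `raw_a`, `raw_b`, `raw_c`.
#' @examples
#' lsbl(0.428, 0.452, 0.083) # branch of the population shared by d_ab, d_ac
#' @export
lsbl <- function(d_ab, d_ac, d_bc) {
  d_ab <- pmax(d_ab, 0); d_ac <- pmax(d_ac, 0); d_bc <- pmax(d_bc, 0)
  a <- (d_ab + d_ac - d_bc) / 2
  b <- (d_ab + d_bc - d_ac) / 2
  c <- (d_ac + d_bc - d_ab) / 2
  tibble(lsbl_a = pmax(a, 0), lsbl_b = pmax(b, 0), lsbl_c = pmax(c, 0),
         raw_a = a, raw_b = b, raw_c = c)
}

#' Per-gene LSBL table from pairwise FST
#'
#' Applies [lsbl()] to per-gene pairwise FST from
#' [differentiation_stats()], labelling branches by population.
#'
#' @param diff_tbl Output of [differentiation_stats()].
#' @param pops The three population labels in design order.
#' @details A pair whose FST is undefined for a gene because no site in the
#'   gene is informative for that pair (all sites monomorphic for the same
#'   allele in both populations) is assigned distance 0 — the two
#'   populations are identical at every observed site — provided another
#'   pair of the gene is defined; genes with no usable sites at all stay
#'   undefined.
#' @return Tibble: `unit_id`, `lsbl_<pop>` and `lsbl_raw_<pop>`.
#' @export
lsbl_table <- function(diff_tbl, pops) {
  assert_that(length(pops) == 3, "LSBL needs exactly three populations")
  col <- function(a, b) {
    nm1 <- paste0("fst_", a, "_", b); nm2 <- paste0("fst_", b, "_", a)
    diff_tbl[[if (nm1 %in% names(diff_tbl)) nm1 else nm2]]
  }
  A <- pops[1]; B <- pops[2]; C <- pops[3]
  d <- cbind(col(A, B), col(A, C), col(B, C))
  some <- rowSums(!is.na(d)) > 0
  d[some, ][is.na(d[some, , drop = FALSE])] <- 0
  dec <- lsbl(d[, 1], d[, 2], d[, 3])
  out <- tibble(unit_id = diff_tbl$unit_id)
  out[[paste0("lsbl_", A)]] <- dec$lsbl_a
  out[[paste0("lsbl_", B)]] <- dec$lsbl_b
  out[[paste0("lsbl_", C)]] <- dec$lsbl_c
  out[[paste0("lsbl_raw_", A)]] <- dec$raw_a
  out[[paste0("lsbl_raw_", B)]] <- dec$raw_b
  out[[paste0("lsbl_raw_", C)]] <- dec$raw_c
  out
}

#' Select candidate genes by LSBL threshold
#'
#' Genes whose branch length for the focal population strictly exceeds the
#' threshold (the boundary value itself is excluded). Also reports how many
#' genes sit at the maximal branch length 1.
#'
#' @param lsbl_tbl Output of [lsbl_table()].
#' @param population Focal population label.
#' @param threshold Selection threshold (default 0.5).
#' @return Tibble of selected genes (`unit_id`, `lsbl`), sorted decreasing;
#'   attribute `n_lsbl_one` counts genes with branch length exactly 1 (to
#'   1e-9).
#' @export
select_by_lsbl <- function(lsbl_tbl, population, threshold = 0.5) {
  col <- paste0("lsbl_", population)
  assert_that(col %in% names(lsbl_tbl), paste("no column", col))
  v <- lsbl_tbl[[col]]
  keep <- !is.na(v) & v > threshold
  out <- tibble(unit_id = lsbl_tbl$unit_id[keep], lsbl = v[keep]) |>
    dplyr::arrange(dplyr::desc(.data$lsbl))
  attr(out, "n_lsbl_one") <- sum(abs(v - 1) < 1e-9, na.rm = TRUE)
  out
}

#' Empirical-quantile outlier genes
#'
#' Flags genes whose statistic reaches the top `1 - q` empirical tail:
#' the `ceiling((1-q) * n)` largest values are flagged, extended to all
#' values tied with the smallest flagged one.
#'
#' @param tbl Per-gene table.
#' @param stat Column name of the statistic.
#' @param q Quantile in (0, 1), default 0.99.
#' @return Tibble of flagged genes (`unit_id`, statistic column), sorted
#'   decreasing; attribute `threshold` is the smallest flagged value.
#' @export
outlier_genes <- function(tbl, stat, q = 0.99) {
  assert_that(q > 0 && q < 1, "quantile must lie in (0, 1)")
  v <- tbl[[stat]]
  ok <- !is.na(v)
  n <- sum(ok)
  assert_that(n >= 20, "need >= 20 genes for a meaningful empirical quantile")
  k <- max(1L, ceiling((1 - q) * n - 1e-9))  # guard float fuzz at exact multiples
  thr <- sort(v[ok], decreasing = TRUE)[k]
  keep <- ok & v >= thr
  out <- tbl[keep, c("unit_id", stat)] |>
    dplyr::arrange(dplyr::desc(.data[[stat]]))
  attr(out, "threshold") <- thr
  out
}

#' Genes flagged by two outlier scans
#'
#' @param a,b Outputs of [outlier_genes()] (or any tibbles with `unit_id`).
#' @return Character vector of shared gene ids.
#' @export
shared_outliers <- function(a, b) {
  intersect(a$unit_id, b$unit_id)
}
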