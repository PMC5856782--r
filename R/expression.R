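#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = 1e9 * count / (library_size * length)`. Library sizes default to
#' column sums of the count matrix. Per-sample rescaling of counts leaves
#' that sample's RPKM vector unchanged.
#'
#' @param counts Tibble with `gene_id` plus one integer column per sample.
#' @param lengths Named vector of gene lengths in bp (> 0), or a tibble
#'   `gene_id`, `length`.
#' @param library_sizes Optional named per-sample library sizes (> 0).
#' @return Tibble of the same shape with RPKM values.
#' @export
rpkm <- function(counts, lengths, library_sizes = NULL) {
  smp <- setdiff(names(counts), "gene_id")
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$gene_id)
  }
  len <- unname(lengths[counts$gene_id])
  assert_that(!anyNA(len), "every gene needs a length")
  assert_that(all(len > 0), "zero-length gene")
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[smp], sum, numeric(1))
  }
  assert_that(all(library_sizes > 0), "library sizes must be positive")
  out <- tibble(gene_id = counts$gene_id)
  for (s in smp) out[[s]] <- 1e9 * counts[[s]] / (library_sizes[[s]] * len)
  out
}

# Vectorised one-way ANOVA on a genes x samples matrix given a grouping
# factor.  Zero within-group variance: equal group means -> p = 1, unequal
# -> p = 0 (documented convention).
anova_p_matrix <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  assert_that(k >= 2, "need >= 2 groups")
  assert_that(all(table(groups) >= 2), "need >= 2 samples per group")
  n <- length(groups)
  gm <- vapply(levels(groups), function(g) rowMeans(x[, groups == g, drop = FALSE]),
               numeric(nrow(x)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1)
  sizes <- as.vector(table(groups))
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(gm, 2, sizes, function(m, s) s * m^2)) - n * grand^2
  # guard tiny negative rounding
  ssb <- pmax(ssb, 0)
  ssw <- rowSums(x^2) - rowSums(sweep(gm^2, 2, sizes, "*"))
  ssw <- pmax(ssw, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  p <- pf(msb / msw, k - 1, n - k, lower.tail = FALSE)
  degen <- msw <= .Machine$double.eps * rowMeans(x^2 + 1)
  p[degen] <- ifelse(msb[degen] <= .Machine$double.eps * (grand[degen]^2 + 1), 1, 0)
  list(p = p, f = msb / msw, df1 = k - 1, df2 = n - k)
}

#' Differential-expression test on log RPKM
#'
#' One-way ANOVA per gene on `log2(RPKM + pseudocount)` across the design's
#' populations, or the two-group special case (equivalent to an
#' equal-variance t-test) when a `pair` is given. Fold change for a pair is
#' the difference of group means of log2 RPKM, oriented from the
#' lower-altitude to the higher-altitude population (positive = higher in
#' the higher-altitude group, altitude order = design level order).
#'
#' @param rpkm_tbl RPKM tibble from [rpkm()].
#' @param design A [pop_design()].
#' @param pair Optional length-2 vector of population labels to compare;
#'   default uses all populations (no fold change reported unless exactly
#'   two).
#' @param pseudocount Added to RPKM before log2 (default 1).
#' @return Tibble: `gene_id`, group mean columns, `log2fc` (pairs only),
#'   `p_value`, `p_adj` (Benjamini-Hochberg).
#' @export
de_test <- function(rpkm_tbl, design, pair = NULL, pseudocount = 1) {
  smp <- setdiff(names(rpkm_tbl), "gene_id")
  missing <- setdiff(smp, design$sample)
  assert_that(length(missing) == 0,
              paste("samples absent from design:", paste(missing, collapse = ", ")))
  dsg <- design[design$sample %in% smp, ]
  if (!is.null(pair)) {
    assert_that(length(pair) == 2 && all(pair %in% pop_levels(design)),
                "pair must name two populations of the design")
    ord <- order(match(pair, pop_levels(design)))
    pair <- pair[ord]                      # lower altitude first
    dsg <- dsg[dsg$population %in% pair, ]
  }
  x <- log2(as.matrix(rpkm_tbl[, dsg$sample, drop = FALSE]) + pseudocount)
  res <- anova_p_matrix(x, dsg$population)
  out <- tibble(gene_id = rpkm_tbl$gene_id)
  for (g in unique(as.character(dsg$population))) {
    out[[paste0("mean_", g)]] <-
      rowMeans(x[, dsg$sample[dsg$population == g], drop = FALSE])
  }
  if (!is.null(pair)) {
    out$log2fc <- out[[paste0("mean_", pair[2])]] - out[[paste0("mean_", pair[1])]]
  }
  out$p_value <- res$p
  out$p_adj <- bh_fdr(res$p)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' `p.adjust(method = "BH")` so the DEG rule reads as stated).
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called iff `p_adj < alpha` AND `|log2fc| > fc_min`; the call is
#' `up` or `down` by the sign of `log2fc` (positive = higher in the
#' higher-altitude group), otherwise `ns`.
#'
#' @param de_tbl Output of [de_test()] with a `log2fc` column.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fc_min Absolute log2 fold-change cutoff (default 1, strict).
#' @return `de_tbl` with an added `call` column.
#' @export
call_degs <- function(de_tbl, alpha = 0.05, fc_min = 1) {
  assert_that("log2fc" %in% names(de_tbl), "de_tbl needs a log2fc column (pairwise test)")
  sig <- de_tbl$p_adj < alpha & abs(de_tbl$log2fc) > fc_min
  de_tbl$call <- ifelse(!sig, "ns", ifelse(de_tbl$log2fc > 0, "up", "down"))
  de_tbl
}

#' Hierarchical clustering of samples on expression
#'
#' Average-linkage agglomeration on `1 - Pearson correlation` of
#' `log2(RPKM + 1)`, optionally restricted to a gene subset (e.g. the DEGs).
#' Samples with constant expression (undefined correlation) are dropped with
#' a warning.
#'
#' @param rpkm_tbl RPKM tibble.
#' @param genes Optional character vector of gene ids to use.
#' @return An `hclust` object.
#' @export
cluster_samples <- function(rpkm_tbl, genes = NULL) {
  if (!is.null(genes)) rpkm_tbl <- rpkm_tbl[rpkm_tbl$gene_id %in% genes, ]
  smp <- setdiff(names(rpkm_tbl), "gene_id")
  assert_that(length(smp) >= 3, "clustering needs >= 3 samples")
  x <- log2(as.matrix(rpkm_tbl[, smp, drop = FALSE]) + 1)
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant-expression sample(s): ",
            paste(smp[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  hclust(as.dist(1 - cor(x)), method = "average")
}

#' Volcano-plot table
#'
#' Pure projection of a DEG table to `(log2fc, -log10 p_adj)` per tested
#' gene.
#'
#' @param de_tbl Output of [de_test()]/[call_degs()].
#' @return Tibble: `gene_id`, `log2fc`, `neg_log10_p_adj` and `call` when
#'   present.
#' @export
volcano_table <- function(de_tbl) {
  out <- tibble(gene_id = de_tbl$gene_id,
                log2fc = de_tbl$log2fc,
                neg_log10_p_adj = -log10(de_tbl$p_adj))
  if ("call" %in% names(de_tbl)) out$call <- de_tbl$call
  out
}
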