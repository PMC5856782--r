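#' Allele-sharing (IBS) distance between samples
#'
#' For a sample pair, the per-site shared-allele score is
#' `2 - |dosage_i - dosage_j|` over sites called in both; the distance is
#' `1 - sum(score) / (2 * n_sites)`, i.e. the mean dosage mismatch halved,
#' lying in [0, 1] (0 for identical genotype vectors, 1 for opposite
#' homozygotes everywhere).
#'
#' @param variants A variant table.
#' @return A symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
allele_sharing_distance <- function(variants) {
  m <- dosage_matrix(variants)
  smp <- colnames(m)
  n <- length(smp)
  d <- matrix(0, n, n, dimnames = list(smp, smp))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(m[, i]) & !is.na(m[, j])
      assert_that(any(both),
                  paste("no overlapping called sites for", smp[i], "and", smp[j]))
      d[i, j] <- d[j, i] <- mean(abs(m[both, i] - m[both, j])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion, as implemented in
#' ape). Negative branch lengths are clamped to 0 for output, with raw
#' values retained in attribute `raw_edge_length`.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @param clamp Clamp negative branch lengths (default TRUE).
#' @return An unrooted `phylo` tree with leaf labels taken from the matrix.
#' @export
neighbor_joining <- function(d, clamp = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  assert_that(nrow(d) >= 3, "neighbor joining needs >= 3 taxa")
  assert_that(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
              "distance matrix must be symmetric")
  tree <- ape::nj(as.dist(d))
  raw <- tree$edge.length
  if (clamp) tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Write / read Newick
#'
#' Thin wrappers over ape's Newick serialisation, so tree output of the
#' pipeline stays in one place.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Check that each population forms a clade of a tree
#'
#' @param tree A `phylo` whose tip labels are sample ids.
#' @param design A [pop_design()].
#' @return Named logical vector, one entry per population.
#' @export
population_monophyly <- function(tree, design) {
  vapply(design_groups(design), function(tips) {
    if (length(tips) <= 1) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, logical(1))
}

#' Genotype PCA with Patterson normalization
#'
#' Builds the samples-by-sites dosage matrix, drops monomorphic sites,
#' imputes missing calls with the site mean dosage, centres each site by
#' `2*p` and (by default) scales by `sqrt(2*p*(1-p))` with `p` the sample
#' alt-allele frequency, then decomposes by SVD. Component signs are fixed
#' by forcing the largest-magnitude loading positive.
#'
#' @param variants A variant table (>= 2 samples, >= 2 polymorphic sites).
#' @param design Optional [pop_design()] carried into the scores table.
#' @param scale Apply the Patterson `sqrt(2p(1-p))` scaling (default TRUE).
#' @return An object of class `altipop_pca`: list with `scores` (tibble:
#'   `sample`, optional `population`, `PC1`, ...), `var_explained`,
#'   `loadings`, `n_sites`.
#' @export
genotype_pca <- function(variants, design = NULL, scale = TRUE) {
  m <- t(dosage_matrix(variants))           # samples x sites
  assert_that(nrow(m) >= 2, "PCA needs >= 2 samples")
  p <- colMeans(m, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  assert_that(sum(poly) >= 2, "PCA needs >= 2 polymorphic sites")
  m <- m[, poly, drop = FALSE]
  p <- p[poly]
  # mean-impute missing calls, centre, optionally scale
  for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- 2 * p[j]
  x <- sweep(m, 2, 2 * p)
  if (scale) x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  s <- svd(x)
  # deterministic sign: largest-magnitude loading of each component positive
  for (k in seq_along(s$d)) {
    i <- which.max(abs(s$v[, k]))
    if (s$v[i, k] < 0) { s$v[, k] <- -s$v[, k]; s$u[, k] <- -s$u[, k] }
  }
  scores <- s$u %*% diag(s$d, nrow = length(s$d))
  colnames(scores) <- paste0("PC", seq_along(s$d))
  tab <- tibble(sample = rownames(m))
  if (!is.null(design)) {
    tab$population <- as.character(design$population[match(tab$sample, design$sample)])
  }
  tab <- dplyr::bind_cols(tab, as_tibble(scores))
  structure(list(scores = tab,
                 var_explained = s$d^2 / sum(s$d^2),
                 loadings = s$v,
                 n_sites = sum(poly)),
            class = "altipop_pca")
}

#' @export
print.altipop_pca <- function(x, ...) {
  cat("<altipop_pca>", nrow(x$scores), "samples,", x$n_sites, "sites\n")
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 2)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "...\n")
  invisible(x)
}

#' Permutation test of group separation
#'
#' Statistic: mean between-group distance minus mean within-group distance,
#' computed either on a distance matrix or on the first `components` of a
#' PCA score space (Euclidean). The p-value uses the add-one convention
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)` over uniform label
#' permutations.
#'
#' @param x An `altipop_pca`, a distance matrix, or a `dist`.
#' @param labels Group label per sample (e.g. `"H"` vs `"LM"`); order must
#'   match the samples of `x`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed for the permutation stream.
#' @param components PCA components used when `x` is an `altipop_pca`
#'   (default first two).
#' @return Tibble: `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test_separation <- function(x, labels, n_perm = 999, seed = NULL,
                                        components = 1:2) {
  assert_that(n_perm >= 99, "use >= 99 permutations")
  if (inherits(x, "altipop_pca")) {
    sc <- as.matrix(x$scores[, paste0("PC", components), drop = FALSE])
    d <- as.matrix(dist(sc))
  } else if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else {
    d <- as.matrix(x)
  }
  labels <- as.character(labels)
  assert_that(length(labels) == nrow(d), "one label per sample required")
  assert_that(length(unique(labels)) >= 2, "need >= 2 groups")
  if (min(table(labels)) < 2) {
    warning("group with a single member: within-group term skipped for it",
            call. = FALSE)
  }
  sep_stat <- function(lab) {
    same <- outer(lab, lab, "==")
    ut <- upper.tri(d)
    between <- d[ut & !same]
    within <- d[ut & same]
    mean(between) - if (length(within)) mean(within) else 0
  }
  obs <- sep_stat(labels)
  perm <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) sep_stat(sample(labels)), numeric(1))
  })
  tibble(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
         n_perm = n_perm)
}
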