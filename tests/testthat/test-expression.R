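# Brute-force BH step-up coded independently of stats::p.adjust.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

test_that("RPKM unit case and invariances", {
  counts <- tibble::tibble(gene_id = "g1", S1 = 1000L)
  r <- rpkm(counts, c(g1 = 1000), library_sizes = c(S1 = 1e6))
  expect_equal(r$S1, 1000)
  # zero counts give zero RPKM; zero length errors
  expect_equal(rpkm(tibble::tibble(gene_id = "g1", S1 = 0L),
                    c(g1 = 500), c(S1 = 100))$S1, 0)
  expect_error(rpkm(counts, c(g1 = 0)), "length")
  # doubling every count of a sample leaves its RPKM unchanged
  cnt <- tibble::tibble(gene_id = paste0("g", 1:5),
                        S1 = c(10L, 20L, 5L, 0L, 100L))
  len <- setNames(c(100, 200, 300, 400, 500), cnt$gene_id)
  r1 <- rpkm(cnt, len)
  cnt2 <- cnt; cnt2$S1 <- cnt2$S1 * 2L
  expect_equal(rpkm(cnt2, len)$S1, r1$S1)
  # one gene with twice the mean of another, same length: RPKM ratio 2
  cnt3 <- tibble::tibble(gene_id = c("a", "b"), S1 = c(200L, 100L))
  r3 <- rpkm(cnt3, c(a = 1000, b = 1000))
  expect_equal(r3$S1[1] / r3$S1[2], 2)
})

test_that("BH adjustment matches the hand case and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  set.seed(51)
  for (rep in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  p <- runif(50)  # p_adj >= p elementwise
  expect_true(all(bh_fdr(p) >= p))
})

test_that("per-gene ANOVA agrees with stats::oneway.test", {
  set.seed(52)
  groups <- factor(rep(c("L", "M", "H"), each = 3))
  x <- matrix(rnorm(30 * 9), 30, 9)
  res <- altipop:::anova_p_matrix(x, groups)
  for (i in c(1, 7, 19, 30)) {
    ref <- oneway.test(x[i, ] ~ groups, var.equal = TRUE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
  # two-group case equals the equal-variance t-test
  g2 <- factor(rep(c("a", "b"), each = 4))
  y <- matrix(rnorm(10 * 8), 10, 8)
  res2 <- altipop:::anova_p_matrix(y, g2)
  for (i in c(2, 9)) {
    ref <- t.test(y[i, g2 == "a"], y[i, g2 == "b"], var.equal = TRUE)
    expect_equal(res2$p[i], ref$p.value, tolerance = 1e-10)
  }
  # degenerate rows: identical values -> p = 1; exact group shift with zero
  # within-variance -> p = 0
  z <- rbind(rep(1, 8), rep(c(0, 1), each = 4))
  res3 <- altipop:::anova_p_matrix(z, g2)
  expect_equal(res3$p, c(1, 0))
})

test_that("DEG direction follows the lower-to-higher altitude convention", {
  d <- toy_design(3)
  cnt <- tibble::tibble(gene_id = c("up_in_H", "down_in_H", "flat"))
  base <- c(100L, 400L, 150L)
  for (s in d$sample) {
    mult <- if (grepl("^H", s)) c(8, 1 / 8, 1) else c(1, 1, 1)
    cnt[[s]] <- as.integer(round(base * mult))
  }
  r <- rpkm(cnt, setNames(rep(1000, 3), cnt$gene_id),
            library_sizes = setNames(rep(1e6, 9), d$sample))
  deg <- call_degs(de_test(r, d, pair = c("M", "H")))
  expect_identical(deg$call[deg$gene_id == "up_in_H"], "up")
  expect_identical(deg$call[deg$gene_id == "down_in_H"], "down")
  expect_identical(deg$call[deg$gene_id == "flat"], "ns")
  expect_gt(deg$log2fc[deg$gene_id == "up_in_H"], 1)
  # swapping the pair order must not flip the convention (design order rules)
  deg2 <- call_degs(de_test(r, d, pair = c("H", "M")))
  expect_identical(deg2$log2fc, deg$log2fc)
})

test_that("DEG rule recovers the simulated truth set", {
  cfg <- sim_config(n_transcripts = 400, de_fraction = 0.1,
                    nb_dispersion = 0.01, seed = 61)
  sim <- simulate_variant_table(cfg)
  ex <- simulate_expression(cfg, sim$annotation)
  r <- rpkm(ex$counts, ex$gene_lengths)
  deg <- call_degs(de_test(r, sim$design, pair = c("M", "H")))
  called <- deg$gene_id[deg$call != "ns"]
  sens <- mean(ex$truth$gene_id %in% called)
  fpr <- mean(setdiff(deg$gene_id, ex$truth$gene_id) %in% called)
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.1)
  # direction agrees with the signed truth
  hit <- deg[deg$gene_id %in% ex$truth$gene_id & deg$call != "ns", ]
  truth_sign <- sign(ex$truth$log2fc[match(hit$gene_id, ex$truth$gene_id)])
  expect_true(all(sign(hit$log2fc) == truth_sign))
})

test_that("identical expression across groups yields no calls", {
  d <- toy_design(2)
  cnt <- tibble::tibble(gene_id = paste0("g", 1:5))
  for (s in d$sample) cnt[[s]] <- c(10L, 50L, 100L, 5L, 0L)
  r <- rpkm(cnt, setNames(rep(1000, 5), cnt$gene_id))
  deg <- call_degs(de_test(r, d, pair = c("L", "H")))
  expect_true(all(deg$call == "ns"))
  expect_true(all(deg$p_value == 1))
})

test_that("sample clustering merges duplicates first and drops constants", {
  set.seed(71)
  cnt <- tibble::tibble(gene_id = paste0("g", 1:50))
  for (s in c("A1", "A2", "B1", "B2")) cnt[[s]] <- rpois(50, 50)
  cnt$A2 <- cnt$A1
  r <- rpkm(cnt, setNames(rep(1000, 50), cnt$gene_id))
  hc <- cluster_samples(r)
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first_pair, c("A1", "A2"))
  # constant sample dropped with warning
  cnt$C1 <- 7L
  r2 <- rpkm(cnt, setNames(rep(1000, 50), cnt$gene_id))
  expect_warning(hc2 <- cluster_samples(r2), "constant")
  expect_false("C1" %in% hc2$labels)
})

test_that("volcano table is a projection of the DEG table", {
  d <- toy_design(2)
  cnt <- tibble::tibble(gene_id = paste0("g", 1:20))
  set.seed(81)
  for (s in d$sample) cnt[[s]] <- rpois(20, 100)
  r <- rpkm(cnt, setNames(rep(1000, 20), cnt$gene_id))
  deg <- call_degs(de_test(r, d, pair = c("M", "H")))
  v <- volcano_table(deg)
  expect_identical(nrow(v), nrow(deg))
  expect_equal(v$neg_log10_p_adj, -log10(deg$p_adj))
})

test_that("DE-gene clustering separates M and H samples in the generator", {
  cfg <- sim_config(n_transcripts = 300, de_fraction = 0.15,
                    nb_dispersion = 0.01, seed = 91)
  sim <- simulate_variant_table(cfg)
  ex <- simulate_expression(cfg, sim$annotation)
  r <- rpkm(ex$counts, ex$gene_lengths)
  deg <- call_degs(de_test(r, sim$design, pair = c("M", "H")))
  called <- deg$gene_id[deg$call != "ns"]
  keep <- c(paste0("M", 1:3), paste0("H", 1:3))
  hc <- cluster_samples(r[, c("gene_id", keep)], genes = called)
  grp <- cutree(hc, 2)
  expect_true(all(grp[paste0("H", 1:3)] != grp[paste0("M", 1:3)]))
})
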