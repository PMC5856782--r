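test_that("generators are bit-identical under a fixed seed and config", {
  cfg <- sim_config(n_transcripts = 60, seed = 7)
  f1 <- simulate_allele_frequencies(cfg)
  f2 <- simulate_allele_frequencies(cfg)
  expect_identical(f1, f2)
  s1 <- simulate_variant_table(cfg)
  s2 <- simulate_variant_table(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$annotation, s2$annotation)
  e1 <- simulate_expression(cfg, s1$annotation)
  e2 <- simulate_expression(cfg, s2$annotation)
  expect_identical(e1$counts, e2$counts)
  m1 <- simulate_meta_studies(0.5, 0.04, 10, 5, seed = 3)
  m2 <- simulate_meta_studies(0.5, 0.04, 10, 5, seed = 3)
  expect_identical(m1, m2)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(divergence_F = c(L = 0, M = 0.1, H = 0.4)), "drift")
  expect_error(sim_config(divergence_F = c(L = 0.1, M = 0.1, H = 1)), "drift")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
})

test_that("Balding-Nichols draw reduces to the ancestral frequency at F = 0", {
  p0 <- runif(50)
  expect_identical(altipop:::bn_draw(p0, 0), p0)
})

test_that("expected FST orders with drift: FST(L,M) << FST(L,H) ~ FST(M,H)", {
  # Monte-Carlo check of the Balding-Nichols expectation on >= 5000 sites,
  # using population (parametric) frequencies from the frequency stage.
  cfg <- sim_config(n_transcripts = 2600,
                    divergence_F = c(L = 0.02, M = 0.02, H = 0.45),
                    private_snp_rate = 0,
                    density_multiplier = c(L = 1, M = 1, H = 1),
                    seed = 13)
  fr <- simulate_allele_frequencies(cfg)
  expect_gt(nrow(fr), 5000)
  param_fst <- function(p1, p2) {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num[den > 0]) / sum(den[den > 0])
  }
  f_lm <- param_fst(fr$p_L, fr$p_M)
  f_lh <- param_fst(fr$p_L, fr$p_H)
  f_mh <- param_fst(fr$p_M, fr$p_H)
  expect_lt(f_lm, f_lh)
  expect_lt(f_lm, f_mh)
  # and monotonicity: raising H's drift raises FST(L,H); the per-run
  # ratio-of-sums estimate is noisy, so contrast well-separated F values
  # on a larger site pool
  fst_at <- function(fh) {
    cfg2 <- sim_config(n_transcripts = 4000,
                       divergence_F = c(L = 0.02, M = 0.02, H = fh),
                       private_snp_rate = 0,
                       density_multiplier = c(L = 1, M = 1, H = 1),
                       seed = 13)
    fr2 <- simulate_allele_frequencies(cfg2)
    param_fst(fr2$p_L, fr2$p_H)
  }
  expect_gt(fst_at(0.7), fst_at(0.2))
})

test_that("genotype dosages are in {0, 1, 2} (or missing when enabled)", {
  sim <- small_sim()
  m <- as.matrix(sim$variants[, variant_samples(sim$variants)])
  expect_true(all(m %in% 0:2))
  cfg <- sim_config(n_transcripts = 40, missing_rate = 0.2, seed = 5)
  sim2 <- simulate_variant_table(cfg)
  m2 <- as.matrix(sim2$variants[, variant_samples(sim2$variants)])
  expect_true(anyNA(m2))
  expect_true(all(m2 %in% c(0:2, NA)))
})

test_that("density multiplier scales realized segregating density (+/- 15%)", {
  cfg <- sim_config(n_transcripts = 1500, seed = 23)
  sim <- simulate_variant_table(cfg)
  expect_gt(nrow(sim$variants), 5000)
  dens <- snp_density(sim$variants, sim$design, sim$annotation,
                      definition = "polymorphic")
  ratio <- dens$density[dens$population == "H"] / dens$density[dens$population == "L"]
  expect_gt(ratio, 1.8 * 0.85)
  expect_lt(ratio, 1.8 * 1.15)
})

test_that("symmetric config gives equal densities within sampling error", {
  cfg <- sim_config(n_transcripts = 1200, private_snp_rate = 0,
                    density_multiplier = c(L = 1, M = 1, H = 1),
                    divergence_F = c(L = 0.1, M = 0.1, H = 0.1),
                    lowland_F = 1e-9, seed = 31)
  sim <- simulate_variant_table(cfg)
  dens <- snp_density(sim$variants, sim$design, sim$annotation,
                      definition = "polymorphic")
  expect_lt(max(dens$density) / min(dens$density), 1.15)
})

test_that("positions are unique within transcripts and inside their bounds", {
  sim <- small_sim()
  expect_false(any(duplicated(sim$variants[, c("transcript_id", "pos")])))
  len <- setNames(sim$annotation$length, sim$annotation$transcript_id)
  expect_true(all(sim$variants$pos >= 1 &
                    sim$variants$pos <= len[sim$variants$transcript_id]))
  expect_true(all(sim$variants$ref != sim$variants$alt))
})

test_that("ref/alt bases follow the configured ts/tv weighting", {
  cfg <- sim_config(n_transcripts = 1500, ts_tv_ratio = 2.7, seed = 17)
  sim <- simulate_variant_table(cfg)
  cls <- classify_substitution(sim$variants$ref, sim$variants$alt)
  ratio <- sum(cls == "transition") / sum(cls == "transversion")
  expect_gt(ratio, 2.7 * 0.85)
  expect_lt(ratio, 2.7 * 1.15)
})

test_that("sweep genes carry fixed differences private to the high population", {
  cfg <- sim_config(n_transcripts = 100, sweep_genes = 10, seed = 3)
  sim <- simulate_variant_table(cfg)
  expect_length(sim$sweep_genes, 10)
  swp <- sim$variants[sim$variants$site_class == "sweep", ]
  expect_true(all(swp$transcript_id %in% sim$sweep_genes))
  h_cols <- paste0("H", 1:3)
  l_cols <- c(paste0("L", 1:3), paste0("M", 1:3))
  expect_true(all(as.matrix(swp[, h_cols]) == 2L))
  expect_true(all(as.matrix(swp[, l_cols]) == 0L))
})

test_that("expression generator honours the DE truth construction", {
  cfg0 <- sim_config(n_transcripts = 80, de_fraction = 0, seed = 9)
  ann <- simulate_variant_table(cfg0)$annotation
  e0 <- simulate_expression(cfg0, ann)
  expect_identical(nrow(e0$truth), 0L)

  cfg <- sim_config(n_transcripts = 80, de_fraction = 0.25, seed = 9)
  e <- simulate_expression(cfg, ann)
  expect_identical(nrow(e$truth), as.integer(round(0.25 * 80)))
  expect_true(all(abs(e$truth$log2fc) == cfg$de_log2fc))
  # DE effect applies to highest-population samples only: means of an
  # up-regulated gene should be ~2^lfc higher in H
  up <- e$truth$gene_id[e$truth$log2fc > 0]
  cmat <- as.matrix(e$counts[, -1])
  rownames(cmat) <- e$counts$gene_id
  h <- paste0("H", 1:3); lm <- c(paste0("L", 1:3), paste0("M", 1:3))
  fold <- rowMeans(cmat[up, h, drop = FALSE] + 1) /
    rowMeans(cmat[up, lm, drop = FALSE] + 1)
  expect_gt(median(fold), 2)
})

test_that("near-zero dispersion approaches Poisson variance", {
  cfg <- sim_config(n_transcripts = 200, samples_per_pop = 30,
                    nb_dispersion = 1e-4, de_fraction = 0, lib_sd = 0,
                    seed = 41)
  ann <- simulate_variant_table(sim_config(n_transcripts = 200, seed = 41))$annotation
  e <- simulate_expression(cfg, ann)
  cmat <- as.matrix(e$counts[, -1])
  vm <- apply(cmat, 1, var) / pmax(rowMeans(cmat), 1e-9)
  # variance/mean ratio concentrates near 1 for Poisson-like counts
  expect_gt(median(vm), 0.7)
  expect_lt(median(vm), 1.4)
})

test_that("meta-study generator validates inputs and concentrates as n grows", {
  expect_error(simulate_meta_studies(0.5, 0.04, 10, 1, seed = 1), "group_n")
  expect_error(simulate_meta_studies(0.5, -1, 10, 5, seed = 1), "tau2")
  big <- simulate_meta_studies(0.8, 0, 20, 5000, seed = 2)
  g <- study_effects(big)$g
  expect_true(all(abs(g - 0.8) < 0.1))
})
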