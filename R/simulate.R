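#' Configuration for the three-population synthetic data generator
#'
#' Builds the parameter set for a seeded generator of transcriptome SNP and
#' expression data with the structure the downstream analyses assume: three
#' populations (by default `L`, `M`, `H` for low/middle/high altitude) of
#' diploid individuals, where `L` and `M` are weakly diverged from each other
#' and both strongly diverged from `H`, `H` carries an elevated
#' segregating-site density and an excess of private SNPs, and a subset of
#' genes is differentially expressed in `H`.
#'
#' Allele frequencies follow a Balding-Nichols beta model on a three-leaf
#' population tree: an ancestral frequency `p0 ~ Beta(a, b)`, a shared
#' "lowland" node drawn from `p0` with drift `lowland_F`, leaves `L` and `M`
#' drawn from the lowland node with their `divergence_F`, and `H` drawn
#' directly from `p0` with its `divergence_F`. Under this model the expected
#' Hudson FST between two leaves equals the mean of their accumulated drift
#' coefficients, so the defaults (`divergence_F = c(L = .055, M = .055,
#' H = .49)`, `lowland_F = 0.25`) target pairwise FST(L,M) ~ 0.07 and
#' FST(L,H) ~ FST(M,H) ~ 0.44 once the population-exclusive (private and
#' density-boost) sites are included.
#'
#' @param n_transcripts Number of transcripts (= genes) to simulate.
#' @param transcript_length_mean,transcript_length_shape Gamma model of
#'   transcript length in bp (mean and shape); lengths below 300 bp are
#'   resampled.
#' @param samples_per_pop Diploid individuals per population.
#' @param pop_labels Ordered population labels, lowest altitude first.
#' @param ancestral_beta Length-2 `(a, b)` of the ancestral frequency Beta.
#' @param divergence_F Named per-population drift coefficients in (0, 1):
#'   for the first two labels drift from the shared lowland node, for the
#'   third drift from the root.
#' @param lowland_F Drift of the shared lowland node from the root.
#' @param snp_rate Per-bp rate of "cosmopolitan" candidate SNP sites (sites
#'   given frequencies in every population).
#' @param density_multiplier Named per-population scalars on the expected
#'   segregating-site density; values above 1 are realised by injecting
#'   population-exclusive segregating sites at a calibrated rate.
#' @param private_snp_rate Per-bp rate, per population, of low-frequency
#'   population-exclusive sites.
#' @param private_beta Length-2 Beta parameters of the private-site allele
#'   frequency (defaults to a rare-allele Beta(1, 9)).
#' @param sweep_genes Number of genes given a population-specific selective
#'   sweep in the highest population: each receives `sweep_sites` sites fixed
#'   for the alt allele in that population and absent elsewhere, providing a
#'   truth set for selection-scan recovery.
#' @param sweep_sites Fixed-difference sites per sweep gene.
#' @param ts_tv_ratio Transition:transversion weighting used when assigning
#'   ref/alt bases.
#' @param missing_rate Probability that a genotype call is missing.
#' @param de_fraction Fraction of genes differentially expressed in the
#'   highest population.
#' @param de_log2fc Absolute log2 fold change of DE genes.
#' @param de_prob_up Probability that a DE gene is up- (rather than down-)
#'   regulated in the highest population.
#' @param nb_dispersion Negative-binomial dispersion of counts (variance =
#'   mu + dispersion * mu^2).
#' @param expr_meanlog,expr_sdlog Lognormal model of per-gene baseline
#'   expression (counts per kb at library factor 1).
#' @param lib_sd Lognormal sd of per-sample library-size factors.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000,
                       transcript_length_mean = 1400,
                       transcript_length_shape = 4,
                       samples_per_pop = 3,
                       pop_labels = c("L", "M", "H"),
                       ancestral_beta = c(0.8, 0.8),
                       divergence_F = c(L = 0.055, M = 0.055, H = 0.49),
                       lowland_F = 0.25,
                       snp_rate = 1.5e-3,
                       density_multiplier = c(L = 1, M = 1, H = 1.8),
                       private_snp_rate = 1e-4,
                       private_beta = c(1, 9),
                       sweep_genes = 0,
                       sweep_sites = 3,
                       ts_tv_ratio = 2.7,
                       missing_rate = 0,
                       de_fraction = 0.1,
                       de_log2fc = 2.0,
                       de_prob_up = 0.68,
                       nb_dispersion = 0.1,
                       expr_meanlog = log(200),
                       expr_sdlog = 1,
                       lib_sd = 0.1,
                       seed = 1L) {
  assert_that(length(pop_labels) == 3, "exactly three population labels expected")
  divergence_F <- divergence_F[pop_labels]
  density_multiplier <- density_multiplier[pop_labels]
  assert_that(!anyNA(divergence_F), "divergence_F must be named by pop_labels")
  assert_that(!anyNA(density_multiplier), "density_multiplier must be named by pop_labels")
  assert_that(all(divergence_F > 0 & divergence_F < 1) && lowland_F > 0 && lowland_F < 1,
              "drift coefficients (divergence_F, lowland_F) must lie in (0, 1)")
  assert_that(n_transcripts > 0 && samples_per_pop > 0, "counts must be positive")
  assert_that(snp_rate > 0 && all(density_multiplier > 0) && private_snp_rate >= 0,
              "rates must be positive")
  assert_that(de_fraction >= 0 && de_fraction <= 1, "de_fraction must lie in [0, 1]")
  assert_that(nb_dispersion > 0, "nb_dispersion must be positive")
  assert_that(missing_rate >= 0 && missing_rate < 1, "missing_rate must lie in [0, 1)")
  assert_that(ts_tv_ratio > 0, "ts_tv_ratio must be positive")
  assert_that(sweep_genes >= 0 && sweep_genes <= n_transcripts,
              "sweep_genes must lie in [0, n_transcripts]")
  assert_that(sweep_sites >= 1, "sweep_sites must be >= 1")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_transcripts, "transcripts,",
      x$samples_per_pop, "samples/pop (", paste(x$pop_labels, collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

# Sample ids in design order: L1, L2, ..., H<k>.
sim_sample_ids <- function(config) {
  unlist(lapply(config$pop_labels,
                function(p) paste0(p, seq_len(config$samples_per_pop))))
}

#' Population design implied by a simulation config
#'
#' @param config A [sim_config()].
#' @return An [pop_design()] mapping generated sample ids to populations.
#' @export
simulate_design <- function(config) {
  pop_design(sim_sample_ids(config),
             rep(config$pop_labels, each = config$samples_per_pop),
             levels = config$pop_labels)
}

# Transcript models (length and UTR/CDS layout) are drawn under their own
# sub-seed so that frequency and variant stages agree on them.
simulate_transcripts <- function(config) {
  with_seed_if(stage_seed(config$seed, "transcripts"), {
    n <- config$n_transcripts
    len <- stats::rgamma(n, shape = config$transcript_length_shape,
                         scale = config$transcript_length_mean / config$transcript_length_shape)
    len <- as.integer(round(pmax(len, 300)))
    utr5 <- pmax(30L, as.integer(round(0.15 * len)))
    cds_len <- pmax(3L, (as.integer(round(0.55 * len)) %/% 3L) * 3L)
    cds_start <- utr5 + 1L
    cds_end <- cds_start + cds_len - 1L
    tibble(
      transcript_id = sprintf("TR%05d", seq_len(n)),
      length = len,
      utr5_start = 1L, utr5_end = utr5,
      cds_start = cds_start, cds_end = cds_end, frame = 0L,
      utr3_start = cds_end + 1L, utr3_end = len,
      covered_bp = len
    )
  })
}

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# One Balding-Nichols step: daughter frequency around p0 with drift F.
bn_draw <- function(p0, F) {
  if (F <= 0) return(p0)
  p0 <- clamp01(p0)
  rbeta(length(p0), p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
}

# Joint leaf frequencies for n sites under the three-leaf drift tree.
bn_tree_freqs <- function(config, n) {
  a <- config$ancestral_beta
  p0 <- rbeta(n, a[1], a[2])
  plow <- bn_draw(p0, config$lowland_F)
  f <- config$divergence_F
  m <- cbind(bn_draw(plow, f[[1]]), bn_draw(plow, f[[2]]), bn_draw(p0, f[[3]]))
  colnames(m) <- config$pop_labels
  list(p0 = p0, leaf = m)
}

# Probability that a site with population frequency p segregates among n
# sampled chromosomes, averaged over the leaf marginal by Monte Carlo.
bn_seg_prob <- function(config, n_chrom, n_mc = 20000) {
  with_seed_if(stage_seed(config$seed, "calibrate"), {
    leaf <- bn_tree_freqs(config, n_mc)$leaf
    colMeans(1 - leaf^n_chrom - (1 - leaf)^n_chrom)
  })
}

# Per-bp rate of extra owner-exclusive segregating sites needed so that the
# expected segregating density of population p is density_multiplier[p] times
# the lowland baseline.  Injected sites are conditioned to segregate, so they
# contribute their rate exactly.
boost_rates <- function(config, seg_prob) {
  base <- mean(seg_prob[1:2]) * config$snp_rate + config$private_snp_rate
  want <- config$density_multiplier * base
  have <- seg_prob * config$snp_rate + config$private_snp_rate
  setNames(pmax(0, want - have), config$pop_labels)
}

# Draw (frequency, alt-allele count among n chromosomes) for owner-exclusive
# sites, conditioned on segregation (count in 1..n-1), by joint rejection.
draw_conditioned_counts <- function(n_sites, n_chrom, draw_p) {
  p <- draw_p(n_sites)
  x <- rbinom(n_sites, n_chrom, p)
  bad <- which(x <= 0 | x >= n_chrom)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    p[bad] <- draw_p(length(bad))
    x[bad] <- rbinom(length(bad), n_chrom, p[bad])
    bad <- bad[x[bad] <= 0 | x[bad] >= n_chrom]
    tries <- tries + 1
  }
  if (length(bad) > 0) { x[bad] <- 1L; p[bad] <- 1 / n_chrom }
  list(p = p, count = as.integer(x))
}

#' Simulate per-site population allele frequencies
#'
#' Draws the site-level frequency table that [simulate_variant_table()] turns
#' into genotypes. Three site classes are produced: `shared` sites carry
#' Balding-Nichols frequencies in every population; `private` sites are
#' low-frequency and exclusive to one population; `boost` sites are
#' population-exclusive segregating sites injected at a rate calibrated so
#' that expected segregating density scales with `density_multiplier`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per candidate site: `transcript_id`,
#'   `site_class`, `owner` (NA for shared sites), ancestral `p0`, one
#'   frequency column per population, and `alt_count` (the conditioned
#'   alt-allele count for owner-exclusive sites, NA otherwise). Transcript
#'   models are attached as attribute `transcripts`.
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- simulate_transcripts(config)
  n_chrom <- 2L * config$samples_per_pop
  seg_prob <- bn_seg_prob(config, n_chrom)
  boost <- boost_rates(config, seg_prob)
  pops <- config$pop_labels

  with_seed_if(stage_seed(config$seed, "frequencies"), {
    pieces <- list()

    n_shared <- rpois(nrow(tr), config$snp_rate * tr$length)
    if (sum(n_shared) > 0) {
      fr <- bn_tree_freqs(config, sum(n_shared))
      shared <- tibble(transcript_id = rep(tr$transcript_id, n_shared),
                       site_class = "shared", owner = NA_character_,
                       p0 = fr$p0)
      for (p in pops) shared[[paste0("p_", p)]] <- fr$leaf[, p]
      shared$alt_count <- NA_integer_
      pieces$shared <- shared
    }

    own_piece <- function(rate, cls, own, draw_p) {
      k <- rpois(nrow(tr), rate * tr$length)
      if (sum(k) == 0) return(NULL)
      dc <- draw_conditioned_counts(sum(k), n_chrom, draw_p)
      out <- tibble(transcript_id = rep(tr$transcript_id, k),
                    site_class = cls, owner = own, p0 = NA_real_)
      for (p in pops) out[[paste0("p_", p)]] <- ifelse(p == own, dc$p, 0)
      out$alt_count <- dc$count
      out
    }

    for (p in pops) {
      pieces[[paste0("priv_", p)]] <- own_piece(
        config$private_snp_rate, "private", p,
        function(k) rbeta(k, config$private_beta[1], config$private_beta[2]))
      if (boost[[p]] > 0) {
        pieces[[paste0("boost_", p)]] <- own_piece(
          boost[[p]], "boost", p,
          function(k) bn_tree_freqs(config, k)$leaf[, p])
      }
    }

    sweep_ids <- character(0)
    if (config$sweep_genes > 0) {
      high <- pops[3]
      sweep_ids <- sort(sample(tr$transcript_id, config$sweep_genes))
      swp <- tibble(transcript_id = rep(sweep_ids, each = config$sweep_sites),
                    site_class = "sweep", owner = high, p0 = NA_real_)
      for (p in pops) swp[[paste0("p_", p)]] <- if (p == high) 1 else 0
      swp$alt_count <- n_chrom
      pieces$sweep <- swp
    }

    out <- dplyr::bind_rows(pieces)
    out <- dplyr::arrange(out, .data$transcript_id)
    attr(out, "transcripts") <- tr
    attr(out, "sweep_genes") <- sweep_ids
    out
  })
}

# Assign alt/ref bases: ref comes from the transcript sequence, alt is a
# transition with probability R/(R+1), otherwise one of the two transversions.
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

draw_alt_bases <- function(ref, ts_tv_ratio) {
  n <- length(ref)
  is_ts <- runif(n) < ts_tv_ratio / (ts_tv_ratio + 1)
  alt <- character(n)
  alt[is_ts] <- TS_PARTNER[ref[is_ts]]
  idx <- which(!is_ts)
  if (length(idx)) {
    pick <- runif(length(idx)) < 0.5
    alt[idx] <- vapply(seq_along(idx),
                       function(i) TV_PARTNERS[[ref[idx[i]]]][if (pick[i]) 1 else 2],
                       character(1))
  }
  alt
}

#' Simulate a variant table and transcript annotation from frequencies
#'
#' Places each candidate site uniformly (without collision) within its
#' transcript, assigns ref/alt bases with the configured
#' transition:transversion weighting against a simulated transcript sequence,
#' and draws diploid genotypes: `Binomial(2, p_pop)` per sample for shared
#' sites, and a random assignment of the conditioned alt-allele count to the
#' owner population's chromosomes for private/boost sites.
#'
#' @param config A [sim_config()].
#' @param freqs Frequency table from [simulate_allele_frequencies()].
#' @return A list of class `altipop_sim` with elements `variants` (tibble:
#'   `transcript_id`, `pos`, `ref`, `alt`, one integer dosage column per
#'   sample; `NA` = missing call), `annotation` (transcript annotation
#'   tibble), `sequences` (tibble `transcript_id`, `sequence`), and `design`.
#' @export
simulate_variant_table <- function(config, freqs = simulate_allele_frequencies(config)) {
  stopifnot(inherits(config, "sim_config"))
  tr <- attr(freqs, "transcripts") %||% simulate_transcripts(config)
  pops <- config$pop_labels
  k <- config$samples_per_pop
  n_chrom <- 2L * k
  samples <- sim_sample_ids(config)

  with_seed_if(stage_seed(config$seed, "variants"), {
    seqs <- vapply(tr$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- tr$transcript_id

    # Positions: uniform within transcript, collision-free by sampling
    # without replacement; surplus sites (rate exceeding length) dropped.
    per_tr <- split(seq_len(nrow(freqs)), factor(freqs$transcript_id, levels = tr$transcript_id))
    pos <- integer(nrow(freqs))
    keep <- rep(TRUE, nrow(freqs))
    for (i in seq_along(per_tr)) {
      idx <- per_tr[[i]]
      if (length(idx) == 0) next
      L <- tr$length[i]
      if (length(idx) > L) { keep[idx[-seq_len(L)]] <- FALSE; idx <- idx[seq_len(L)] }
      pos[idx] <- sample.int(L, length(idx))
    }
    freqs <- freqs[keep, , drop = FALSE]
    pos <- pos[keep]

    ref <- substring(seqs[freqs$transcript_id], pos, pos)
    alt <- draw_alt_bases(ref, config$ts_tv_ratio)

    n_sites <- nrow(freqs)
    G <- matrix(0L, n_sites, length(samples), dimnames = list(NULL, samples))
    shared <- is.na(freqs$owner)
    for (pi in seq_along(pops)) {
      p <- pops[pi]
      cols <- paste0(p, seq_len(k))
      pv <- freqs[[paste0("p_", p)]]
      if (any(shared)) {
        G[shared, cols] <- matrix(rbinom(sum(shared) * k, 2, rep(pv[shared], k)),
                                  ncol = k)
      }
      own <- which(!shared & freqs$owner == p)
      for (s in own) {
        chrom <- integer(n_chrom)
        chrom[sample.int(n_chrom, freqs$alt_count[s])] <- 1L
        G[s, cols] <- chrom[seq(1, n_chrom, 2)] + chrom[seq(2, n_chrom, 2)]
      }
    }
    if (config$missing_rate > 0) {
      G[runif(length(G)) < config$missing_rate] <- NA_integer_
    }

    variants <- tibble(transcript_id = freqs$transcript_id,
                       pos = as.integer(pos),
                       ref = ref, alt = alt,
                       site_class = freqs$site_class,
                       owner = freqs$owner)
    for (s in samples) variants[[s]] <- G[, s]
    variants <- dplyr::arrange(variants, .data$transcript_id, .data$pos)

    structure(list(variants = variants,
                   annotation = tr,
                   sequences = tibble(transcript_id = tr$transcript_id,
                                      sequence = unname(seqs)),
                   design = simulate_design(config),
                   sweep_genes = attr(freqs, "sweep_genes") %||% character(0)),
              class = "altipop_sim")
  })
}

#' Simulate an expression count matrix with a DE truth table
#'
#' Per-gene negative-binomial counts with mean
#' `baseline * length/1e3 * library_factor`, multiplied by `2^(log2fc)` in
#' samples of the highest population for genes drawn as differentially
#' expressed. The signed truth table supports sensitivity / false-call
#' evaluation of the DEG rule.
#'
#' @param config A [sim_config()].
#' @param annotation Transcript annotation (provides gene ids and lengths).
#' @return List of class `altipop_expr_sim`: `counts` (tibble `gene_id` +
#'   one integer column per sample), `gene_lengths` (named vector),
#'   `truth` (tibble `gene_id`, `log2fc` for DE genes), `lib_factors`.
#' @export
simulate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$nb_dispersion > 0, "nb_dispersion must be positive")
  samples <- sim_sample_ids(config)
  high <- paste0(config$pop_labels[3], seq_len(config$samples_per_pop))
  n_genes <- nrow(annotation)

  with_seed_if(stage_seed(config$seed, "expression"), {
    baseline <- rlnorm(n_genes, config$expr_meanlog, config$expr_sdlog)
    lib <- rlnorm(length(samples), 0, config$lib_sd)
    names(lib) <- samples

    n_de <- round(config$de_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    sign_up <- runif(length(de_idx)) < config$de_prob_up
    lfc <- numeric(n_genes)
    lfc[de_idx] <- ifelse(sign_up, config$de_log2fc, -config$de_log2fc)

    counts <- tibble(gene_id = annotation$transcript_id)
    for (s in samples) {
      mu <- baseline * annotation$length / 1e3 * lib[[s]]
      if (s %in% high) mu <- mu * 2^lfc
      counts[[s]] <- rnbinom(n_genes, mu = mu, size = 1 / config$nb_dispersion)
    }

    structure(list(counts = counts,
                   gene_lengths = setNames(annotation$length, annotation$transcript_id),
                   truth = tibble(gene_id = annotation$transcript_id[de_idx],
                                  log2fc = lfc[de_idx]),
                   lib_factors = lib),
              class = "altipop_expr_sim")
  })
}

#' Simulate raw summary statistics for meta-analysis studies
#'
#' Draws `n_studies` two-group studies under a random-effects model:
#' study-level true standardized effects are `Normal(true_effect, tau2)`, and
#' each group contributes `group_n` unit-variance normal observations.
#'
#' @param true_effect True standardized mean difference.
#' @param tau2 Between-study variance (>= 0).
#' @param n_studies Number of studies.
#' @param group_n Observations per group (>= 2; the sd of a single
#'   observation is undefined).
#' @param seed Optional integer seed.
#' @param moderator Optional numeric covariate per study (recycled/checked);
#'   stored alongside for meta-regression.
#' @return Tibble: `study`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, and
#'   `moderator` when supplied.
#' @export
simulate_meta_studies <- function(true_effect, tau2, n_studies, group_n,
                                  seed = NULL, moderator = NULL) {
  assert_that(tau2 >= 0, "tau2 must be non-negative")
  assert_that(group_n >= 2, "group_n must be >= 2 (sd undefined otherwise)")
  with_seed_if(seed, {
    theta <- rnorm(n_studies, true_effect, sqrt(tau2))
    one <- function(i) {
      g1 <- rnorm(group_n, theta[i], 1)
      g2 <- rnorm(group_n, 0, 1)
      c(mean(g1), sd(g1), mean(g2), sd(g2))
    }
    m <- t(vapply(seq_len(n_studies), one, numeric(4)))
    out <- tibble(study = paste0("S", seq_len(n_studies)),
                  mean1 = m[, 1], sd1 = m[, 2], n1 = group_n,
                  mean2 = m[, 3], sd2 = m[, 4], n2 = group_n)
    if (!is.null(moderator)) {
      assert_that(length(moderator) == n_studies,
                  "moderator must have one value per study")
      out$moderator <- moderator
    }
    out
  })
}

#' Simulate a complete dataset (variants + annotation + expression)
#'
#' Convenience wrapper running the whole generator chain under one config.
#'
#' @param config A [sim_config()].
#' @return An `altipop_sim` list with an additional `expression` element.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_variant_table(config)
  sim$expression <- simulate_expression(config, sim$annotation)
  sim
}

#' Write a simulated dataset to plain-text files
#'
#' Writes VCF 4.2 (`variants.vcf`), a tab-separated transcript annotation
#' (`annotation.tsv`, 1-based inclusive intervals), a counts matrix
#' (`counts.tsv`), gene lengths (`gene_lengths.tsv`), and a two-column
#' sample-to-population table (`populations.tsv`).
#'
#' @param sim An `altipop_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    populations = file.path(dir, "populations.tsv")
  )
  write_vcf(sim$variants, paths[["vcf"]],
            contig_lengths = setNames(sim$annotation$length, sim$annotation$transcript_id))
  readr::write_tsv(sim$annotation, paths[["annotation"]])
  write_pop_design(sim$design, paths[["populations"]])
  if (!is.null(sim$expression)) {
    paths[["counts"]] <- file.path(dir, "counts.tsv")
    paths[["gene_lengths"]] <- file.path(dir, "gene_lengths.tsv")
    readr::write_tsv(sim$expression$counts, paths[["counts"]])
    readr::write_tsv(tibble(gene_id = names(sim$expression$gene_lengths),
                            length = unname(sim$expression$gene_lengths)),
                     paths[["gene_lengths"]])
    paths[["de_truth"]] <- file.path(dir, "de_truth.tsv")
    readr::write_tsv(sim$expression$truth, paths[["de_truth"]])
  }
  invisible(paths)
}
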