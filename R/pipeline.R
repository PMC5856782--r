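#' Configuration for the end-to-end analysis pipeline
#'
#' One config drives the whole chain: simulate (or load) data, SNP
#' descriptive statistics, diversity, differentiation + LSBL, structure
#' (NJ/PCA/permutation), differential expression, ABC on SNP density, and
#' the pseudo-study meta-analysis. A single global seed is split into
#' per-stage streams by stable stage names, so disabling one stage does not
#' perturb the others.
#'
#' @param out_dir Output directory of the run.
#' @param seed Global integer seed.
#' @param sim A [sim_config()]; its own seed is overridden by the pipeline's
#'   `simulate` stage seed.
#' @param stages Character vector of stages to run, a subset of the default.
#' @param lsbl_threshold LSBL candidate threshold.
#' @param outlier_q Empirical outlier quantile for FST/GST scans.
#' @param deg_pair Two population labels compared for DEGs (default the two
#'   highest).
#' @param deg_alpha,deg_fc_min DEG rule cutoffs.
#' @param abc_n_sims,abc_tolerance ABC simulation budget and acceptance
#'   fraction.
#' @param meta_per_set Pseudo-studies per site.
#' @param altitudes Named altitudes (m) used as meta-regression moderator.
#' @param n_perm Permutations for the structure test.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = sim_config(),
                            stages = c("simulate", "snpstats", "diversity",
                                       "differentiation", "structure",
                                       "expression", "abc", "meta"),
                            lsbl_threshold = 0.5,
                            outlier_q = 0.99,
                            deg_pair = NULL,
                            deg_alpha = 0.05,
                            deg_fc_min = 1,
                            abc_n_sims = 5000,
                            abc_tolerance = 0.02,
                            meta_per_set = 9,
                            altitudes = c(L = 2846, M = 3282, H = 3714),
                            n_perm = 999) {
  known <- c("simulate", "snpstats", "diversity", "differentiation",
             "structure", "expression", "abc", "meta")
  assert_that(all(stages %in% known),
              paste("unknown stage(s):", paste(setdiff(stages, known), collapse = ", ")))
  structure(as.list(environment()), class = "pipeline_config")
}

pipe_log <- function(run_dir, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage plain-text
#' outputs under `out_dir` and a `manifest.json` listing every output file
#' with an MD5 content hash. Rerunning with an identical config and seed
#' reproduces identical hashes. A stage failure writes a `FAILED` marker
#' naming the stage (partial outputs are retained) and rethrows the error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list (`files`, `seed`, `stages`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_dir <- config$out_dir
  unlink(file.path(run_dir, "FAILED"))
  outputs <- character(0)
  note <- function(paths) outputs <<- c(outputs, unname(paths))
  state <- new.env(parent = emptyenv())
  current_stage <- "setup"

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    current_stage <<- name
    pipe_log(run_dir, name, "start")
    fn(stage_seed(config$seed, name))
    pipe_log(run_dir, name, "done")
  }

  tryCatch({
    run_stage("simulate", function(seed) {
      sim_cfg <- config$sim
      sim_cfg$seed <- seed
      state$sim <- simulate_dataset(sim_cfg)
      note(write_sim_dataset(state$sim, file.path(run_dir, "data")))
    })

    need_sim <- function() {
      assert_that(!is.null(state$sim),
                  "downstream stages need the simulate stage in this run")
      state$sim
    }

    run_stage("snpstats", function(seed) {
      sim <- need_sim()
      dens <- snp_density(sim$variants, sim$design, sim$annotation,
                          mode = "individual")
      spec <- spectrum_counts(sim$variants, sim$design)
      venn <- private_shared_sets(sim$variants, sim$design)
      eff <- classify_coding_effect(sim$variants, sim$annotation, sim$sequences)
      eff_counts <- dplyr::count(eff, .data$effect)
      p <- c(density = file.path(run_dir, "snp_density.tsv"),
             density_per_sample = file.path(run_dir, "snp_density_per_sample.tsv"),
             spectrum = file.path(run_dir, "spectrum.tsv"),
             tstv = file.path(run_dir, "ts_tv.tsv"),
             venn = file.path(run_dir, "private_shared.tsv"),
             effects = file.path(run_dir, "coding_effect_counts.tsv"))
      readr::write_tsv(dens, p[["density"]])
      readr::write_tsv(attr(dens, "per_sample"), p[["density_per_sample"]])
      readr::write_tsv(spec, p[["spectrum"]])
      readr::write_tsv(attr(spec, "ts_tv"), p[["tstv"]])
      readr::write_tsv(venn, p[["venn"]])
      readr::write_tsv(eff_counts, p[["effects"]])
      state$density <- dens
      note(p)
    })

    run_stage("diversity", function(seed) {
      sim <- need_sim()
      div <- diversity_stats(sim$variants, sim$design, sim$annotation, by = "gene")
      gen <- diversity_stats(sim$variants, sim$design, sim$annotation, by = "genome")
      bins <- div |>
        dplyr::group_by(.data$population) |>
        dplyr::group_modify(~d_threshold_bins(.x$tajima_d)) |>
        dplyr::ungroup()
      p <- c(gene = file.path(run_dir, "diversity_gene.tsv"),
             genome = file.path(run_dir, "diversity_genome.tsv"),
             bins = file.path(run_dir, "tajima_d_bins.tsv"))
      readr::write_tsv(div, p[["gene"]])
      readr::write_tsv(gen, p[["genome"]])
      readr::write_tsv(bins, p[["bins"]])
      state$diversity <- div
      note(p)
    })

    run_stage("differentiation", function(seed) {
      sim <- need_sim()
      pops <- pop_levels(sim$design)
      diff_gene <- differentiation_stats(sim$variants, sim$design, by = "gene")
      diff_genome <- differentiation_stats(sim$variants, sim$design, by = "genome")
      lsb <- lsbl_table(diff_gene, pops)
      cand <- select_by_lsbl(lsb, pops[3], config$lsbl_threshold)
      pair_hl <- paste0("fst_", pops[1], "_", pops[3])
      fst_out <- outlier_genes(dplyr::filter(diff_gene, !is.na(.data[[pair_hl]])),
                               pair_hl, config$outlier_q)
      gst_out <- outlier_genes(dplyr::filter(diff_gene, !is.na(.data$gst)),
                               "gst", config$outlier_q)
      p <- c(gene = file.path(run_dir, "differentiation_gene.tsv"),
             genome = file.path(run_dir, "differentiation_genome.tsv"),
             lsbl = file.path(run_dir, "lsbl_gene.tsv"),
             candidates = file.path(run_dir, "lsbl_candidates.txt"),
             fst_outliers = file.path(run_dir, "fst_outliers.txt"),
             gst_outliers = file.path(run_dir, "gst_outliers.txt"),
             shared_outliers = file.path(run_dir, "shared_outliers.txt"))
      readr::write_tsv(diff_gene, p[["gene"]])
      readr::write_tsv(diff_genome, p[["genome"]])
      readr::write_tsv(lsb, p[["lsbl"]])
      writeLines(cand$unit_id, p[["candidates"]])
      writeLines(fst_out$unit_id, p[["fst_outliers"]])
      writeLines(gst_out$unit_id, p[["gst_outliers"]])
      writeLines(shared_outliers(fst_out, gst_out), p[["shared_outliers"]])
      state$differentiation <- list(gene = diff_gene, genome = diff_genome,
                                    lsbl = lsb, candidates = cand)
      note(p)
    })

    run_stage("structure", function(seed) {
      sim <- need_sim()
      pops <- pop_levels(sim$design)
      d <- allele_sharing_distance(sim$variants)
      tree <- neighbor_joining(d)
      pca <- genotype_pca(sim$variants, sim$design)
      grp <- ifelse(sim$design$population == pops[3], pops[3], "lowland")
      perm <- permutation_test_separation(pca, grp, n_perm = config$n_perm,
                                          seed = seed)
      p <- c(dist = file.path(run_dir, "distance_matrix.tsv"),
             tree = file.path(run_dir, "nj_tree.nwk"),
             scores = file.path(run_dir, "pca_scores.tsv"),
             varexp = file.path(run_dir, "pca_variance.tsv"),
             perm = file.path(run_dir, "permutation_test.tsv"))
      readr::write_tsv(as_tibble(d, rownames = "sample"), p[["dist"]])
      write_newick(tree, p[["tree"]])
      readr::write_tsv(tidy(pca), p[["scores"]])
      readr::write_tsv(glance(pca), p[["varexp"]])
      readr::write_tsv(perm, p[["perm"]])
      state$structure <- list(tree = tree, pca = pca, perm = perm)
      note(p)
    })

    run_stage("expression", function(seed) {
      sim <- need_sim()
      pops <- pop_levels(sim$design)
      pair <- config$deg_pair %||% pops[2:3]
      rk <- rpkm(sim$expression$counts, sim$expression$gene_lengths)
      deg <- call_degs(de_test(rk, sim$design, pair = pair),
                       alpha = config$deg_alpha, fc_min = config$deg_fc_min)
      volc <- volcano_table(deg)
      called <- deg$gene_id[deg$call != "ns"]
      p <- c(rpkm = file.path(run_dir, "rpkm.tsv"),
             deg = file.path(run_dir, "deg.tsv"),
             volcano = file.path(run_dir, "volcano.tsv"))
      readr::write_tsv(rk, p[["rpkm"]])
      readr::write_tsv(deg, p[["deg"]])
      readr::write_tsv(volc, p[["volcano"]])
      if (length(called) >= 2) {
        hc <- cluster_samples(rk, genes = called)
        p[["dendrogram"]] <- file.path(run_dir, "expression_dendrogram.nwk")
        write_newick(ape::as.phylo(hc), p[["dendrogram"]])
      }
      state$expression <- list(rpkm = rk, deg = deg)
      note(p)
    })

    run_stage("abc", function(seed) {
      sim <- need_sim()
      pops <- pop_levels(sim$design)
      obs <- observed_density_summaries(sim$variants, sim$design, sim$annotation)
      rk <- state$expression$rpkm %||%
        rpkm(sim$expression$counts, sim$expression$gene_lengths)
      transcripts <- tibble(length = sim$annotation$length,
                            expression = rowMeans(as.matrix(rk[, -1])))
      # uniform priors bracketing the observed density scale by x10 each way
      scale <- mean(obs$mean_density) / 1e6
      priors <- c(setNames(lapply(pops, function(p) c(scale / 10, scale * 10)),
                           paste0("mu_", pops)),
                  list(kappa = c(1e-3, 10), sigma_rpkm = c(0, 1)))
      cfg <- abc_config(priors, n_sims = config$abc_n_sims,
                        tolerance_quantile = config$abc_tolerance, seed = seed)
      post <- abc_rejection(obs, cfg, transcripts)
      bif <- bifurcation_test(post, high = paste0("mu_", pops[3]),
                              low = paste0("mu_", pops[1:2]))
      p <- c(observed = file.path(run_dir, "abc_observed.tsv"),
             posterior = file.path(run_dir, "abc_posterior.tsv"),
             summary = file.path(run_dir, "abc_summary.tsv"),
             decision = file.path(run_dir, "abc_decision.json"))
      readr::write_tsv(obs, p[["observed"]])
      readr::write_tsv(tidy(post), p[["posterior"]])
      readr::write_tsv(glance(post), p[["summary"]])
      jsonlite::write_json(as.list(bif), p[["decision"]], auto_unbox = TRUE,
                           digits = NA)
      state$abc <- list(posterior = post, bifurcation = bif)
      note(p)
    })

    run_stage("meta", function(seed) {
      sim <- need_sim()
      pops <- pop_levels(sim$design)
      dens <- state$density %||%
        snp_density(sim$variants, sim$design, sim$annotation, mode = "individual")
      per_sample <- attr(dens, "per_sample")
      studies <- randomize_studies(per_sample$density, per_sample$population,
                                   per_set = config$meta_per_set, seed = seed)
      effects <- dplyr::bind_rows(lapply(pops[-1], function(tgt) {
        study_effects(contrast_studies(studies, target = tgt,
                                       reference = pops[1],
                                       moderator = config$altitudes[[tgt]]))
      }))
      pooled <- pool_random_effects(effects)
      reg <- meta_regression(effects, effects$moderator)
      p <- c(studies = file.path(run_dir, "meta_studies.tsv"),
             effects = file.path(run_dir, "meta_effects.tsv"),
             pooled = file.path(run_dir, "meta_pooled.json"),
             regression = file.path(run_dir, "meta_regression.tsv"))
      readr::write_tsv(studies, p[["studies"]])
      readr::write_tsv(effects, p[["effects"]])
      jsonlite::write_json(glance(pooled), p[["pooled"]], auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      readr::write_tsv(reg, p[["regression"]])
      state$meta <- list(pooled = pooled, regression = reg, effects = effects)
      note(p)
    })
  }, error = function(e) {
    writeLines(paste("stage:", current_stage, "-", conditionMessage(e)),
               file.path(run_dir, "FAILED"))
    stop("pipeline failed in stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    files = lapply(setNames(outputs, sub(paste0("^", run_dir, "/?"), "", outputs)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}
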