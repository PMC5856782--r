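test_that("VCF round trip preserves the canonical table", {
  sim <- small_sim()
  tbl <- sim$variants[1:200, c("transcript_id", "pos", "ref", "alt",
                               variant_samples(sim$variants))]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tbl, path)
  back <- read_vcf(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), ignore_attr = TRUE)
  expect_identical(attr(back, "n_skipped"), 0L)
})

test_that("empty VCF body reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t")), path)
  tbl <- read_vcf(path)
  expect_identical(nrow(tbl), 0L)
})

test_that("non-biallelic records are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
               "T1\t5\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
               "T1\t9\t.\tA\tG,C\t.\tPASS\t.\tGT\t1/2\t0/0",
               "T1\t12\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0"), path)
  expect_message(tbl <- read_vcf(path), "skipped")
  expect_identical(nrow(tbl), 1L)
  expect_identical(attr(tbl, "n_skipped"), 2L)
  expect_identical(tbl$S1, 1L)
})

test_that("missing genotypes round-trip as ./.", {
  tbl <- make_variants(matrix(c(0, 1, NA, 2), 2, 2), samples = c("A1", "B1"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tbl, path)
  back <- read_vcf(path)
  expect_identical(back$A1, c(0L, 1L))
  expect_identical(back$B1, c(NA_integer_, 2L))
})

test_that("transition/transversion classification follows the definition", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("G", "A"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("G", "C"), "transversion")
  expect_identical(classify_substitution("A", "T"), "transversion")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("N", "A"), "base")
})

test_that("spectrum counts sum to table size and give the ts/tv ratio", {
  # 27 A->G (transitions) and 10 A->C (transversions) -> ts/tv = 2.7
  tbl <- make_variants(matrix(1, 37, 2), samples = c("S1", "S2"),
                       ref = "A", alt = c(rep("G", 27), rep("C", 10)))
  spec <- spectrum_counts(tbl)
  expect_identical(sum(spec$n), 37L)
  tstv <- attr(spec, "ts_tv")
  expect_equal(tstv$ts_tv[tstv$population == "all"], 2.7)
  by_class <- tapply(spec$n, spec$class, sum)
  expect_identical(unname(by_class["transition"] + by_class["transversion"]), 37L)
})

test_that("per-population spectra use sites present in the population", {
  d <- toy_design(1)
  tbl <- make_variants(cbind(c(1, 0), c(0, 0), c(0, 2)),
                       samples = c("L1", "M1", "H1"),
                       ref = c("A", "C"), alt = c("G", "A"))
  spec <- spectrum_counts(tbl, d)
  n_of <- function(pop, r, a) {
    spec$n[spec$population == pop & spec$ref == r & spec$alt == a]
  }
  expect_identical(n_of("L", "A", "G"), 1L)
  expect_identical(n_of("L", "C", "A"), 0L)
  expect_identical(n_of("H", "C", "A"), 1L)
  expect_identical(sum(spec$n[spec$population == "M"]), 0L)
})

test_that("snp density arithmetic and modes", {
  d <- toy_design(1)
  ann <- make_annotation("T1", 1000000L)
  tbl <- make_variants(cbind(rep(1, 10), rep(0, 10), rep(0, 10)),
                       samples = c("L1", "M1", "H1"))
  dens <- snp_density(tbl, d, ann)
  expect_equal(dens$density[dens$population == "L"], 10)
  expect_equal(dens$density[dens$population == "M"], 0)
  # no segregating sites at all
  tbl0 <- make_variants(cbind(rep(0, 3), rep(0, 3), rep(0, 3)),
                        samples = c("L1", "M1", "H1"))
  dens0 <- snp_density(tbl0, d, ann)
  expect_true(all(dens0$density == 0))
  # individual mode reports mean +/- sd across samples
  d2 <- toy_design(2)
  tbl2 <- make_variants(cbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                        samples = d2$sample)
  di <- snp_density(tbl2, d2, ann, mode = "individual")
  expect_equal(di$density[di$population == "L"], mean(c(2, 1)))
  expect_equal(di$density_sd[di$population == "L"], sd(c(2, 1)))
  expect_error(snp_density(tbl2, d2, make_annotation("T1", 0L)), "covered")
})

test_that("private/shared Venn regions partition the segregating sites", {
  d <- toy_design(1)
  tbl <- make_variants(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), c(1, 0, 1, 1)),
                       samples = c("L1", "M1", "H1"))
  venn <- private_shared_sets(tbl, d)
  get <- function(r) venn$n[venn$region == r]
  expect_identical(get("H"), 1L)     # alt only in H
  expect_identical(get("L"), 1L)
  expect_identical(get("L&M&H"), 1L) # triple intersection only
  expect_identical(get("M&H"), 1L)
  expect_identical(sum(venn$n), attr(venn, "n_present"))

  sim <- small_sim()
  v2 <- private_shared_sets(sim$variants, sim$design)
  seg_any <- sum(rowSums(sim$variants[, variant_samples(sim$variants)],
                         na.rm = TRUE) > 0)
  expect_identical(sum(v2$n), seg_any)
})

test_that("high population accumulates the private-SNP excess", {
  sim <- small_sim()
  venn <- private_shared_sets(sim$variants, sim$design)
  n_of <- function(r) venn$n[venn$region == r]
  expect_gt(n_of("H"), 2 * n_of("L"))
  expect_gt(n_of("H"), 2 * n_of("M"))
})

test_that("coding-effect classification matches codon-table expectations", {
  # transcript: 1-6 UTR5, CDS 7-15 (ATG CTT TAA layout), UTR3 16-30
  ann <- tibble::tibble(transcript_id = "T1", length = 30L,
                        utr5_start = 1L, utr5_end = 6L,
                        cds_start = 7L, cds_end = 15L, frame = 0L,
                        utr3_start = 16L, utr3_end = 30L, covered_bp = 30L)
  seqs <- tibble::tibble(transcript_id = "T1",
                         sequence = paste0("ACACAC", "ATGCTTTAC", "GTGTGTGTGTGTGTG"))
  tbl <- make_variants(matrix(1, 4, 2), samples = c("S1", "S2"),
                       pos = c(12L, 9L, 20L, 3L),
                       ref = c("T", "G", "T", "A"),
                       alt = c("C", "A", "A", "G"))
  eff <- classify_coding_effect(tbl, ann, seqs)
  expect_identical(eff$effect[1], "synonymous")       # CTT -> CTC, Leu
  expect_identical(eff$effect[2], "non-synonymous")   # ATG -> ATA, Met -> Ile
  expect_identical(eff$effect[3], "utr3")
  expect_identical(eff$effect[4], "utr5")
  expect_identical(eff$aa_ref[1], "L")
  expect_identical(eff$aa_alt[1], "L")
  expect_identical(eff$aa_alt[2], "I")
})

test_that("stop gain is non-synonymous and flagged; partial codons warn", {
  ann <- tibble::tibble(transcript_id = "T1", length = 20L,
                        utr5_start = NA_integer_, utr5_end = NA_integer_,
                        cds_start = 1L, cds_end = 10L, frame = 0L,
                        utr3_start = NA_integer_, utr3_end = NA_integer_,
                        covered_bp = 20L)
  seqs <- tibble::tibble(transcript_id = "T1", sequence = "TACAAATTTGGGGGGGGGGG")
  # TAC -> TAA (pos 3 C->A): Tyr -> stop
  tbl <- make_variants(matrix(1, 2, 2), samples = c("S1", "S2"),
                       pos = c(3L, 10L), ref = c("C", "G"), alt = c("A", "T"))
  expect_warning(eff <- classify_coding_effect(tbl, ann, seqs), "partial codon")
  expect_identical(eff$effect[1], "non-synonymous")
  expect_true(eff$stop_flag[1])
  expect_identical(eff$effect[2], "noncoding")  # trailing base of 10-bp CDS
})

test_that("codon classification agrees with full-CDS re-translation", {
  # brute-force oracle: translate whole ref and mutated CDS with Biostrings
  set.seed(20)
  code <- Biostrings::GENETIC_CODE
  for (rep in 1:10) {
    cds_len <- 3 * sample(4:20, 1)
    cds_start <- sample(1:10, 1)
    len <- cds_start + cds_len + sample(0:10, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    ann <- tibble::tibble(transcript_id = "T1", length = len,
                          utr5_start = NA_integer_, utr5_end = NA_integer_,
                          cds_start = cds_start,
                          cds_end = cds_start + cds_len - 1L, frame = 0L,
                          utr3_start = NA_integer_, utr3_end = NA_integer_,
                          covered_bp = len)
    pos <- sample(cds_start:(cds_start + cds_len - 1), 5)
    ref <- substring(seq, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    tbl <- make_variants(matrix(1, 5, 2), samples = c("S1", "S2"),
                         pos = as.integer(pos), ref = ref, alt = alt)
    eff <- classify_coding_effect(tbl, ann, tibble::tibble(transcript_id = "T1",
                                                           sequence = seq))
    for (i in seq_len(5)) {
      cds_ref <- substring(seq, cds_start, cds_start + cds_len - 1)
      mutated <- cds_ref
      substr(mutated, pos[i] - cds_start + 1, pos[i] - cds_start + 1) <- alt[i]
      aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_ref)))
      aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mutated)))
      expected <- if (aa_ref == aa_alt) "synonymous" else "non-synonymous"
      expect_identical(eff$effect[i], expected)
    }
  }
})
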