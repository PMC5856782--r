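#' Read a variant table from VCF
#'
#' Reads a VCF 4.x file (via vcfR) into the package's variant-table form:
#' one row per biallelic SNP with per-sample alt-allele dosages. Records that
#' are not biallelic SNPs (multi-allelic sites, indels, symbolic alleles) are
#' skipped; the number skipped is reported in a message and attached as
#' attribute `n_skipped`.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @return A tibble with columns `transcript_id` (from CHROM), `pos`, `ref`,
#'   `alt`, and one integer dosage column (0/1/2, `NA` = missing) per sample.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(transcript_id = character(), pos = integer(),
                  ref = character(), alt = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  bases <- c("A", "C", "G", "T")
  ok <- fix$REF %in% bases & fix$ALT %in% bases
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"] %||% "")) {
    stop("VCF has no GT field", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  dos <- apply(gt, 2, function(g) {
    g <- gsub("\\|", "/", g)
    d <- rep(NA_integer_, length(g))
    d[g %in% c("0/0")] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g %in% c("1/1")] <- 2L
    d
  })
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = sum(ok))
  colnames(dos) <- colnames(gt)
  out <- tibble(transcript_id = fix$CHROM,
                pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  for (s in colnames(dos)) out[[s]] <- unname(dos[, s])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant table as VCF 4.2
#'
#' Emits a minimal plain-text VCF 4.2 with GT-only genotypes, one contig per
#' transcript. `read_vcf(write_vcf(x))` round-trips the canonical columns and
#' dosages bit-identically.
#'
#' @param variants A variant table.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig (transcript)
#'   lengths for `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  smp <- variant_samples(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=altipop",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", smp), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(0)
  if (nrow(variants) > 0) {
    gt_cols <- lapply(smp, function(s) {
      d <- variants[[s]]
      ifelse(is.na(d), "./.", gt_code[d + 1L])
    })
    body <- do.call(paste, c(list(variants$transcript_id, variants$pos, ".",
                                  variants$ref, variants$alt, ".", "PASS",
                                  ".", "GT"), gt_cols, sep = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify substitutions as transitions or transversions
#'
#' A substitution is a transition iff it stays within purines (`A<->G`) or
#' within pyrimidines (`C<->T`); all other base changes are transversions.
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T).
#' @return Character vector: `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution(c("A", "G"), c("G", "C"))
#' @export
classify_substitution <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  assert_that(all(ref %in% bases) && all(alt %in% bases),
              "ref and alt must be single bases in {A,C,G,T}")
  assert_that(all(ref != alt), "ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Directed mutation-spectrum counts and ts/tv ratio
#'
#' Counts variants in the 12 directed `ref -> alt` substitution classes.
#' With a design, per-population spectra are computed over the sites carrying
#' at least one alt allele in that population.
#'
#' @param variants A variant table.
#' @param design Optional [pop_design()]; when given, spectra are reported
#'   per population (plus a pooled `"all"` row set).
#' @return A tibble `population`, `ref`, `alt`, `class`, `n`, with an
#'   attribute `ts_tv` carrying the transition/transversion ratio per
#'   population.
#' @export
spectrum_counts <- function(variants, design = NULL) {
  all_classes <- tidyr::expand_grid(ref = c("A", "C", "G", "T"),
                                    alt = c("A", "C", "G", "T"))
  all_classes <- all_classes[all_classes$ref != all_classes$alt, ]
  one_spectrum <- function(tbl, label) {
    cnt <- dplyr::count(tbl, .data$ref, .data$alt)
    out <- dplyr::left_join(all_classes, cnt, by = c("ref", "alt"))
    out$n[is.na(out$n)] <- 0L
    out$class <- classify_substitution(out$ref, out$alt)
    dplyr::bind_cols(tibble(population = label), out)
  }
  sets <- list(all = variants)
  if (!is.null(design)) {
    check_design_covers(design, variants)
    for (p in pop_levels(design)) {
      cols <- design$sample[design$population == p]
      present <- rowSums(variants[, cols, drop = FALSE], na.rm = TRUE) > 0
      sets[[p]] <- variants[present, , drop = FALSE]
    }
  }
  out <- dplyr::bind_rows(lapply(names(sets), function(nm) one_spectrum(sets[[nm]], nm)))
  tstv <- out |>
    dplyr::group_by(.data$population, .data$class) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n") |>
    dplyr::mutate(ts_tv = .data$transition / .data$transversion)
  attr(out, "ts_tv") <- tstv
  out
}

# Per-population alt-allele and called-chromosome counts per site.
pop_allele_counts <- function(variants, design) {
  check_design_covers(design, variants)
  pops <- pop_levels(design)
  n_sites <- nrow(variants)
  alt <- called <- matrix(0, n_sites, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- design$sample[design$population == p]
    sub <- as.matrix(variants[, cols, drop = FALSE])
    alt[, p] <- rowSums(sub, na.rm = TRUE)
    called[, p] <- 2 * rowSums(!is.na(sub))
  }
  list(alt = alt, called = called)
}

#' Per-population SNP density
#'
#' Density in SNPs per covered megabase. In `"population"` mode a site counts
#' for a population when it carries at least one alt allele among that
#' population's samples (`definition = "presence"`, the default) or when it
#' is polymorphic within the population (`definition = "polymorphic"`). In
#' `"individual"` mode each sample's SNP count (sites with dosage >= 1) is
#' divided by the covered length and summarised as mean and sd per
#' population, mirroring the usual "density +/- sd" presentation.
#'
#' @param variants A variant table.
#' @param design A [pop_design()].
#' @param annotation Transcript annotation supplying `covered_bp`.
#' @param mode `"population"` or `"individual"`.
#' @param definition Site-presence rule for population mode.
#' @return A tibble with `population`, `n_snps` (population mode),
#'   `density` (SNPs/Mb) and, in individual mode, `density_sd` and
#'   `n_samples`. Per-sample counts are attached as attribute `per_sample`.
#' @export
snp_density <- function(variants, design, annotation,
                        mode = c("population", "individual"),
                        definition = c("presence", "polymorphic")) {
  mode <- match.arg(mode)
  definition <- match.arg(definition)
  covered_mb <- sum(annotation$covered_bp) / 1e6
  assert_that(covered_mb > 0, "total covered length must be positive")
  counts <- pop_allele_counts(variants, design)
  pops <- pop_levels(design)
  if (mode == "population") {
    n_snps <- vapply(pops, function(p) {
      a <- counts$alt[, p]; nc <- counts$called[, p]
      if (definition == "presence") sum(a > 0) else sum(a > 0 & a < nc)
    }, numeric(1))
    return(tibble(population = pops, n_snps = as.integer(n_snps),
                  covered_mb = covered_mb, density = n_snps / covered_mb))
  }
  per_sample <- tibble(
    sample = design$sample,
    population = as.character(design$population),
    n_snps = vapply(design$sample,
                    function(s) sum(variants[[s]] >= 1, na.rm = TRUE), numeric(1)))
  per_sample$density <- per_sample$n_snps / covered_mb
  out <- per_sample |>
    dplyr::group_by(population = factor(.data$population, levels = pops)) |>
    dplyr::summarise(density_sd = sd(.data$density),
                     density = mean(.data$density),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(population = as.character(.data$population)) |>
    dplyr::select("population", "density", "density_sd", "n_samples")
  attr(out, "per_sample") <- per_sample[, c("sample", "population", "n_snps", "density")]
  out
}

#' Private and shared SNP counts (Venn regions)
#'
#' A SNP is "present" in a population iff at least one alt allele is carried
#' by its samples (threshold configurable as a minimum alt-allele frequency).
#' Each segregating site falls in exactly one presence region (private to one
#' population, shared by a specific pair, ... up to the full intersection),
#' so region counts partition the segregating-site set.
#'
#' @param variants A variant table.
#' @param design A [pop_design()].
#' @param min_freq Minimum within-population alt-allele frequency for
#'   presence; the default `0` means any single alt allele.
#' @return A tibble `region` (labels like `"H"` or `"L&M"`), `n`. Sites with
#'   no alt allele anywhere are excluded and counted in attribute
#'   `n_absent`; attribute `n_present` gives the partition total.
#' @export
private_shared_sets <- function(variants, design, min_freq = 0) {
  pops <- pop_levels(design)
  assert_that(length(pops) >= 2, "need at least two populations")
  counts <- pop_allele_counts(variants, design)
  freq <- counts$alt / pmax(counts$called, 1)
  present <- counts$alt > 0 & freq > min_freq
  region <- apply(present, 1, function(r) paste(pops[r], collapse = "&"))
  keep <- region != ""
  all_regions <- unlist(lapply(seq_along(pops), function(k)
    utils::combn(pops, k, paste, collapse = "&", simplify = TRUE)))
  tab <- table(factor(region[keep], levels = all_regions))
  out <- tibble(region = names(tab), n = as.integer(tab))
  attr(out, "n_absent") <- sum(!keep)
  attr(out, "n_present") <- sum(keep)
  out
}

#' Classify variants by coding effect
#'
#' Assigns each variant to a transcript region (5'UTR, CDS, 3'UTR,
#' noncoding) and, within the CDS, translates the containing codon with the
#' ref and with the alt base under the standard nuclear genetic code:
#' identical amino acids give `synonymous`, otherwise `non-synonymous`
#' (stop gain/loss is non-synonymous and additionally flagged). Bases of a
#' trailing partial codon (CDS length not divisible by 3 after the frame
#' offset) are treated as noncoding with a warning.
#'
#' @param variants A variant table.
#' @param annotation Transcript annotation with `utr5_*`, `cds_*`, `frame`,
#'   `utr3_*` columns (1-based inclusive).
#' @param sequences Tibble `transcript_id`, `sequence` with the transcript
#'   reference sequences.
#' @return The variant table with added columns `region`, `effect`,
#'   `aa_ref`, `aa_alt`, `stop_flag`.
#' @export
classify_coding_effect <- function(variants, annotation, sequences) {
  code <- Biostrings::GENETIC_CODE
  ann <- annotation[match(variants$transcript_id, annotation$transcript_id), ]
  seqv <- sequences$sequence[match(variants$transcript_id, sequences$transcript_id)]
  assert_that(!anyNA(ann$transcript_id), "variants reference transcripts absent from annotation")

  pos <- variants$pos
  region <- rep("noncoding", nrow(variants))
  region[!is.na(ann$utr5_start) & pos >= ann$utr5_start & pos <= ann$utr5_end] <- "utr5"
  region[!is.na(ann$utr3_start) & pos >= ann$utr3_start & pos <= ann$utr3_end] <- "utr3"
  in_cds <- pos >= ann$cds_start & pos <= ann$cds_end
  region[in_cds] <- "cds"

  effect <- region
  aa_ref <- aa_alt <- rep(NA_character_, nrow(variants))
  stop_flag <- rep(FALSE, nrow(variants))

  idx <- which(in_cds)
  if (length(idx)) {
    offset <- pos[idx] - (ann$cds_start[idx] + ann$frame[idx])
    codon_start <- ann$cds_start[idx] + ann$frame[idx] + (offset %/% 3L) * 3L
    trailing <- offset < 0 | codon_start + 2L > ann$cds_end[idx]
    if (any(trailing)) {
      warning(sum(trailing),
              " CDS variant(s) in a partial codon treated as noncoding",
              call. = FALSE)
      effect[idx[trailing]] <- "noncoding"
      region[idx[trailing]] <- "noncoding"
    }
    cidx <- idx[!trailing]
    if (length(cidx)) {
      cs <- codon_start[!trailing]
      codon <- substring(seqv[cidx], cs, cs + 2L)
      within <- pos[cidx] - cs + 1L
      sub_at <- function(codon, at, base) {
        substr(codon, at, at) <- base
        codon
      }
      codon_ref <- mapply(sub_at, codon, within, variants$ref[cidx], USE.NAMES = FALSE)
      codon_alt <- mapply(sub_at, codon, within, variants$alt[cidx], USE.NAMES = FALSE)
      aa_r <- unname(code[codon_ref])
      aa_a <- unname(code[codon_alt])
      aa_ref[cidx] <- aa_r
      aa_alt[cidx] <- aa_a
      effect[cidx] <- ifelse(aa_r == aa_a, "synonymous", "non-synonymous")
      stop_flag[cidx] <- (aa_r == "*") != (aa_a == "*")
    }
  }
  out <- variants
  out$region <- region
  out$effect <- effect
  out$aa_ref <- aa_ref
  out$aa_alt <- aa_alt
  out$stop_flag <- stop_flag
  out
}
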