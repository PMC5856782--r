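# Internal helpers shared across modules.

# Columns of a variant table that are not per-sample genotype dosages.
variant_meta_cols <- function(x) {
  intersect(c("transcript_id", "pos", "ref", "alt", "site_class", "owner"), names(x))
}

#' Sample columns of a variant table
#'
#' @param variants A variant table as produced by [simulate_variant_table()]
#'   or [read_vcf()].
#' @return Character vector of sample column names.
#' @export
variant_samples <- function(variants) {
  setdiff(names(variants), variant_meta_cols(variants))
}

# Sites x samples integer dosage matrix (NA = missing call).
dosage_matrix <- function(variants) {
  smp <- variant_samples(variants)
  m <- as.matrix(variants[, smp, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# Derive a per-stage RNG seed from a global seed and a stable stage name, so
# enabling/disabling one stage never perturbs the stream of another.
stage_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h * 7919) %% 2147483629 + 1)
}

# Evaluate expr under a local seed when one is given, leaving the caller's RNG
# stream untouched; with seed = NULL the ambient stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
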