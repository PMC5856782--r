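# Small in-code fixtures shared across test files.

# Variant table from a sites x samples dosage matrix.
make_variants <- function(dosages, samples = NULL, transcript = "T1",
                          ref = "A", alt = "G", pos = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  samples <- samples %||% paste0("S", seq_len(ncol(dosages)))
  out <- tibble::tibble(transcript_id = rep(transcript, length.out = n),
                        pos = pos %||% seq_len(n),
                        ref = rep(ref, length.out = n),
                        alt = rep(alt, length.out = n))
  for (j in seq_along(samples)) out[[samples[j]]] <- as.integer(dosages[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal annotation for one or more transcripts of equal covered length.
make_annotation <- function(transcript_id = "T1", length = 1000L) {
  tibble::tibble(transcript_id = transcript_id,
                 length = as.integer(length),
                 utr5_start = 1L, utr5_end = 100L,
                 cds_start = 101L, cds_end = 700L, frame = 0L,
                 utr3_start = 701L, utr3_end = as.integer(length),
                 covered_bp = as.integer(length))
}

# Three-population toy design: k samples per pop named L1.., M1.., H1..
toy_design <- function(k = 2) {
  pop_design(unlist(lapply(c("L", "M", "H"), function(p) paste0(p, seq_len(k)))),
             rep(c("L", "M", "H"), each = k))
}

# A small simulated dataset cached per test run (generation is fast but this
# avoids repeating it in every test block).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_transcripts = 300, seed = 101))
    }
    cache
  }
})
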