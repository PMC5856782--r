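#' Construct a population design
#'
#' A population design maps each sample to a population label and fixes the
#' order of the labels (lowest to highest altitude by convention, so that
#' differential-expression direction and pairwise contrasts are well defined).
#'
#' @param sample Character vector of sample identifiers.
#' @param population Character vector of population labels, parallel to
#'   `sample`.
#' @param levels Ordered unique population labels; defaults to order of first
#'   appearance.
#' @return A tibble with columns `sample` and `population` (a factor with the
#'   given levels), of class `altipop_design`.
#' @examples
#' pop_design(c("L1", "L2", "H1", "H2"), c("L", "L", "H", "H"))
#' @export
pop_design <- function(sample, population, levels = unique(population)) {
  assert_that(length(sample) == length(population),
              "`sample` and `population` must have equal length")
  assert_that(!anyDuplicated(sample), "duplicated sample ids in design")
  assert_that(all(population %in% levels),
              "every population label must appear in `levels`")
  out <- tibble(sample = as.character(sample),
                population = factor(population, levels = levels))
  class(out) <- c("altipop_design", class(out))
  out
}

pop_levels <- function(design) levels(design$population)

# Named list: population label -> character vector of its sample ids.
design_groups <- function(design) {
  split(design$sample, design$population)
}

check_design_covers <- function(design, variants, min_per_pop = 1) {
  smp <- variant_samples(variants)
  missing <- setdiff(smp, design$sample)
  assert_that(length(missing) == 0,
              paste("samples absent from design:", paste(missing, collapse = ", ")))
  sizes <- table(design$population[design$sample %in% smp])
  assert_that(all(sizes >= min_per_pop),
              sprintf("every population needs >= %d samples", min_per_pop))
  invisible(TRUE)
}

#' Read / write a two-column sample-to-population table
#'
#' Plain TSV with columns `sample` and `population`; row order of first
#' appearance fixes the population level order.
#'
#' @param path File path.
#' @return For `read_pop_design()`, an `altipop_design`.
#' @export
read_pop_design <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  pop_design(x$sample, x$population)
}

#' @rdname read_pop_design
#' @param design An `altipop_design`.
#' @export
write_pop_design <- function(design, path) {
  readr::write_tsv(tibble(sample = design$sample,
                          population = as.character(design$population)), path)
  invisible(path)
}
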