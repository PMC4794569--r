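#' Label vocabularies
#'
#' Fixed, ordered label sets used throughout the package: the seven
#' antinuclear-antibody staining patterns recognised on HEp-2 substrate
#' cells, the three fluorescence intensity classes a reader assigns to a
#' well, and the two mitotic fluorescence types. Serialized names are
#' lowercase snake_case and round-trip unchanged through manifests and
#' reports.
#'
#' @return Character vector of labels, in canonical order.
#' @examples
#' hep2_patterns()
#' hep2_intensities()
#' @export
hep2_patterns <- function() {
  c("homogeneous", "fine_speckled", "coarse_speckled", "nucleolar",
    "centromere", "nuclear_dots", "nuclear_pore_complex")
}

#' @rdname hep2_patterns
#' @export
hep2_intensities <- function() {
  c("negative", "intermediate", "positive")
}

#' @rdname hep2_patterns
#' @export
hep2_mitosis_types <- function() {
  c("positive_mitosis", "negative_mitosis")
}

assert_label <- function(label, vocabulary, what = "label") {
  if (length(label) != 1L || !is.character(label) || !(label %in% vocabulary)) {
    stop(sprintf("unknown %s '%s'; expected one of: %s", what,
                 paste(label, collapse = ","),
                 paste(vocabulary, collapse = ", ")), call. = FALSE)
  }
  label
}

assert_pattern <- function(label) assert_label(label, hep2_patterns(), "staining pattern")
assert_intensity <- function(label) assert_label(label, hep2_intensities(), "intensity class")
assert_mitosis_type <- function(label) assert_label(label, hep2_mitosis_types(), "mitosis type")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All generators route randomness
# through this so they are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds from a parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
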