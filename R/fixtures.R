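#' Packaged reference tables
#'
#' Two small fixtures ship with the package for exercising the agreement
#' statistics on published summary numbers:
#'
#' * `senior_reader_concordance()` — the 7-class count matrix of two senior
#'   immunofluorescence readers double-reading 589 wells (negative plus six
#'   staining patterns), as an `hep2_confusion`.
#' * `cad_reference_confusion()` — the row-normalized (percent) pattern
#'   confusion of a reference CAD system against a gold-standard reading;
#'   its `"other"` class has no gold examples and is excluded from mean
#'   class accuracy by [mean_class_accuracy()].
#'
#' @return `senior_reader_concordance()`: an `hep2_confusion`;
#'   `cad_reference_confusion()`: a numeric percentage matrix.
#' @examples
#' cm <- senior_reader_concordance()
#' round(100 * accuracy(cm))      # observed concordance, percent
#' round(cohens_kappa(cm), 2)
#' @export
senior_reader_concordance <- function() {
  path <- system.file("extdata", "senior_reader_concordance.csv",
                      package = "hep2cad", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$class
  as_confusion(m, df$class)
}

#' @rdname senior_reader_concordance
#' @export
cad_reference_confusion <- function() {
  path <- system.file("extdata", "cad_reference_confusion_pct.csv",
                      package = "hep2cad", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(reference = df$class, prediction = df$class)
  m
}
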