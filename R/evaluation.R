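#' Confusion matrix
#'
#' Square labeled count matrix over a fixed, ordered class list. Rows index
#' the reference labels (or reader A), columns the predictions (or reader
#' B). This is the substrate of all agreement statistics in the package.
#'
#' @param ref_labels,pred_labels Equal-length label vectors.
#' @param classes Ordered class list; every label must belong to it.
#' @return An object of class `hep2_confusion`: `classes`, `counts`
#'   (with dimnames), `N`.
#' @examples
#' cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "b"), c("a", "b"))
#' accuracy(cm)
#' @export
confusion_matrix <- function(ref_labels, pred_labels, classes) {
  if (length(ref_labels) != length(pred_labels)) {
    stop("label vectors must have equal length")
  }
  bad <- setdiff(unique(c(ref_labels, pred_labels)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(ref_labels, levels = classes),
                  factor(pred_labels, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(reference = classes, prediction = classes))
  new_confusion(counts, classes)
}

#' @rdname confusion_matrix
#' @param counts A square count matrix (rows = reference).
#' @export
as_confusion <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            length(classes) == nrow(counts))
  dimnames(counts) <- list(reference = classes, prediction = classes)
  new_confusion(counts, classes)
}

new_confusion <- function(counts, classes) {
  structure(list(classes = classes, counts = counts, N = sum(counts)),
            class = "hep2_confusion")
}

#' @export
print.hep2_confusion <- function(x, ...) {
  cat(sprintf("confusion matrix over %d classes, N = %d\n",
              length(x$classes), x$N))
  print(x$counts)
  invisible(x)
}

#' Per-class correct classification rate
#'
#' `CCR_k = T_k / N_k`: the diagonal count of class `k` over its reference
#' (row) total. Undefined — an error — when the class has no reference
#' elements.
#'
#' @param cm An `hep2_confusion`.
#' @param class_k A class label.
#' @return A proportion in \[0, 1\].
#' @export
ccr <- function(cm, class_k) {
  stopifnot(inherits(cm, "hep2_confusion"))
  if (!class_k %in% cm$classes) stop("unknown class: ", class_k)
  nk <- sum(cm$counts[class_k, ])
  if (nk == 0) stop("CCR undefined: class '", class_k, "' has no reference elements")
  cm$counts[class_k, class_k] / nk
}

#' Overall accuracy
#'
#' The class-size-weighted mean of per-class correct classification rates,
#' which reduces to the trace of the confusion matrix over its total count.
#'
#' @param cm An `hep2_confusion`.
#' @return A proportion in \[0, 1\].
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "hep2_confusion"))
  if (cm$N == 0) stop("accuracy undefined for an empty matrix")
  sum(diag(cm$counts)) / cm$N
}

#' Mean class accuracy (MAC)
#'
#' The unweighted mean of per-class correct classification rates. Classes
#' with no reference elements are excluded (and reported via the
#' `"excluded"` attribute); with equal class sizes MAC equals [accuracy()].
#'
#' @param x An `hep2_confusion`, or a numeric vector of per-class rates.
#' @return A proportion, with attribute `excluded` listing skipped classes.
#' @export
mean_class_accuracy <- function(x) {
  if (is.numeric(x)) {
    if (!length(x)) stop("no rates supplied")
    return(mean(x))
  }
  stopifnot(inherits(x, "hep2_confusion"))
  nk <- rowSums(x$counts)
  keep <- nk > 0
  if (!any(keep)) stop("MAC undefined: every class is empty")
  rates <- diag(x$counts)[keep] / nk[keep]
  structure(mean(rates), excluded = x$classes[!keep])
}

#' Cohen's kappa
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/N` and expected agreement
#' `p_e = sum_i row_i * col_i / N^2`. Returns exactly 1 for perfect
#' agreement even when `p_e = 1`.
#'
#' @param cm An `hep2_confusion`.
#' @return A value in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "hep2_confusion"))
  if (cm$N == 0) stop("kappa undefined for an empty matrix")
  po <- sum(diag(cm$counts)) / cm$N
  pe <- sum(rowSums(cm$counts) * colSums(cm$counts)) / cm$N^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' McNemar test for paired proportions
#'
#' Tests symmetry of the two discordant counts of a paired design. The
#' exact mode is the two-sided binomial test of `b` successes in `b + c`
#' trials at probability one half; the corrected mode is the chi-square
#' statistic `(|b - c| - 1)^2 / (b + c)` with continuity correction. With
#' `mode = "auto"` the exact test is used when `b + c < 25`. No discordance
#' at all gives `p = 1` by convention.
#'
#' @param n_discordant_ab,n_discordant_ba The discordant counts `b` and `c`.
#' @param mode `"auto"`, `"exact"` or `"corrected"`.
#' @return List with `statistic` (`NA` for exact), `p_value`, `mode`.
#' @export
mcnemar_test <- function(n_discordant_ab, n_discordant_ba, mode = c("auto", "exact", "corrected")) {
  mode <- match.arg(mode)
  b <- n_discordant_ab; c <- n_discordant_ba
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) return(list(statistic = NA_real_, p_value = 1, mode = "none"))
  if (mode == "auto") mode <- if (n < 25) "exact" else "corrected"
  if (mode == "exact") {
    lo <- min(b, c)
    p <- 2 * stats::pbinom(lo, n, 0.5)
    if (b == c) p <- 1   # the two tails overlap at the centre
    list(statistic = NA_real_, p_value = min(1, p), mode = "exact")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         mode = "corrected")
  }
}

#' Pearson chi-square test of independence
#'
#' Applied to a confusion matrix after dropping all-zero rows and columns
#' (reported in the result); expected counts are the usual outer product of
#' the margins over N.
#'
#' @param cm An `hep2_confusion`.
#' @return List with `statistic`, `df`, `p_value`, `dropped` (labels).
#' @export
chi_square_independence <- function(cm) {
  stopifnot(inherits(cm, "hep2_confusion"))
  if (cm$N == 0) stop("chi-square undefined for an empty matrix")
  keep_r <- rowSums(cm$counts) > 0
  keep_c <- colSums(cm$counts) > 0
  dropped <- union(cm$classes[!keep_r], cm$classes[!keep_c])
  m <- cm$counts[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("fewer than 2 nonempty rows or columns; chi-square not applicable")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), dropped = dropped)
}

#' Two-reader agreement report
#'
#' Builds the confusion matrix of two paired label assignments and derives
#' observed agreement, Cohen's kappa, per-class correct classification
#' rates in both directions (rows-as-reference and columns-as-reference),
#' and the chi-square test of independence.
#'
#' @param labels_a,labels_b Paired label vectors (reader A rows, B columns).
#' @param classes Ordered class list.
#' @return An `hep2_agreement_report`.
#' @export
agreement_report <- function(labels_a, labels_b, classes) {
  cm <- confusion_matrix(labels_a, labels_b, classes)
  agreement_report_from_confusion(cm)
}

#' @rdname agreement_report
#' @param cm A precomputed `hep2_confusion` (e.g. a packaged fixture).
#' @export
agreement_report_from_confusion <- function(cm) {
  po <- accuracy(cm)
  per_a <- vapply(cm$classes, function(k) {
    if (sum(cm$counts[k, ]) == 0) NA_real_ else ccr(cm, k)
  }, 0)
  cmt <- as_confusion(t(cm$counts), cm$classes)
  per_b <- vapply(cm$classes, function(k) {
    if (sum(cmt$counts[k, ]) == 0) NA_real_ else ccr(cmt, k)
  }, 0)
  chis <- tryCatch(chi_square_independence(cm), error = function(e) NULL)
  structure(list(confusion = cm, observed_agreement = po,
                 kappa = cohens_kappa(cm),
                 per_class_ccr = list(rows_as_reference = per_a,
                                      cols_as_reference = per_b),
                 chi_square = chis, n = cm$N),
            class = "hep2_agreement_report")
}

#' @export
print.hep2_agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d paired reads: %.0f%% observed, kappa %.2f\n",
              x$n, 100 * x$observed_agreement, x$kappa))
  print(x$confusion$counts)
  invisible(x)
}

#' Second-reader support simulation
#'
#' Combines a human reader's calls with CAD calls under a configurable
#' policy and reports accuracy, MAC and kappa against a gold standard
#' before and after support. Policies: `"never"` keeps the reader's calls;
#' `"always"` takes the CAD call; `"confidence"` (default) keeps the
#' reader's call unless the CAD disagrees with confidence above
#' `threshold`.
#'
#' @param reader_labels,cad_labels,gold_labels Aligned label vectors.
#' @param classes Ordered class list.
#' @param policy One of `"confidence"`, `"never"`, `"always"`.
#' @param cad_confidence Numeric CAD confidence per call (defaults to 1).
#' @param threshold Confidence needed to override the reader.
#' @return List with `assisted_labels`, `before` and `after` metric lists,
#'   and the deltas.
#' @export
reader_with_cad <- function(reader_labels, cad_labels, gold_labels, classes,
                            policy = c("confidence", "never", "always"),
                            cad_confidence = NULL, threshold = 0.5) {
  policy <- match.arg(policy)
  n <- length(gold_labels)
  if (length(reader_labels) != n || length(cad_labels) != n) {
    stop("reader, CAD and gold label vectors must be aligned")
  }
  if (is.null(cad_confidence)) cad_confidence <- rep(1, n)
  assisted <- switch(policy,
    never = reader_labels,
    always = cad_labels,
    confidence = ifelse(cad_labels != reader_labels & cad_confidence > threshold,
                        cad_labels, reader_labels))
  metrics <- function(lab) {
    cm <- confusion_matrix(gold_labels, lab, classes)
    list(accuracy = accuracy(cm),
         mac = as.numeric(mean_class_accuracy(cm)),
         kappa = cohens_kappa(cm))
  }
  before <- metrics(reader_labels)
  after <- metrics(assisted)
  list(assisted_labels = assisted, before = before, after = after,
       delta = list(accuracy = after$accuracy - before$accuracy,
                    mac = after$mac - before$mac,
                    kappa = after$kappa - before$kappa))
}

#' Evaluate predictions against reference labels
#'
#' Convenience wrapper joining two well-level label tables on `well_id` and
#' reporting the confusion matrix, accuracy, MAC, per-class CCR and kappa.
#'
#' @param pred,ref Data frames with columns `well_id` and `label`.
#' @param classes Ordered class list.
#' @return List of metrics plus the confusion matrix.
#' @export
evaluate_labels <- function(pred, ref, classes) {
  stopifnot(all(c("well_id", "label") %in% names(pred)),
            all(c("well_id", "label") %in% names(ref)))
  unmatched <- c(setdiff(ref$well_id, pred$well_id),
                 setdiff(pred$well_id, ref$well_id))
  if (length(unmatched)) {
    stop("well_ids without a counterpart: ", paste(unique(unmatched), collapse = ", "))
  }
  pred <- pred[match(ref$well_id, pred$well_id), ]
  cm <- confusion_matrix(ref$label, pred$label, classes)
  per <- vapply(classes, function(k) {
    if (sum(cm$counts[k, ]) == 0) NA_real_ else ccr(cm, k)
  }, 0)
  list(confusion = cm, accuracy = accuracy(cm),
       mac = as.numeric(mean_class_accuracy(cm)),
       kappa = cohens_kappa(cm), per_class_ccr = per)
}
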