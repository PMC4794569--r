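test_that("confusion matrices equal a brute-force tally", {
  cls <- c("a", "b", "c")
  set.seed(5)
  ref <- sample(cls, 60, replace = TRUE)
  pred <- sample(cls, 60, replace = TRUE)
  cm <- confusion_matrix(ref, pred, cls)
  brute <- matrix(0L, 3, 3, dimnames = list(cls, cls))
  for (i in seq_along(ref)) {
    brute[ref[i], pred[i]] <- brute[ref[i], pred[i]] + 1L
  }
  expect_equal(unname(cm$counts), unname(brute))
  expect_equal(cm$N, 60)

  perfect <- confusion_matrix(ref, ref, cls)
  expect_equal(sum(diag(perfect$counts)), 60)

  empty <- confusion_matrix(character(), character(), cls)
  expect_equal(empty$N, 0)
  expect_error(confusion_matrix("a", "z", cls), "unknown label")
  expect_error(confusion_matrix(c("a", "b"), "a", cls), "equal length")
})

test_that("per-class rates, accuracy and MAC follow their definitions", {
  set.seed(11)
  m <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
  cls <- letters[1:4]
  cm <- as_confusion(m, cls)
  expect_equal(accuracy(cm), sum(diag(m)) / sum(m))
  # accuracy == weighted mean of CCRs (the defining identity)
  rates <- vapply(cls, function(k) ccr(cm, k), 0)
  nk <- rowSums(m)
  expect_equal(accuracy(cm), sum(rates * nk) / sum(nk))
  expect_equal(as.numeric(mean_class_accuracy(cm)), mean(rates))

  # MAC is invariant to class reordering and count rescaling
  perm <- c(3, 1, 4, 2)
  expect_equal(as.numeric(mean_class_accuracy(as_confusion(m[perm, perm], cls[perm]))),
               as.numeric(mean_class_accuracy(cm)))
  expect_equal(as.numeric(mean_class_accuracy(as_confusion(m * 10L, cls))),
               as.numeric(mean_class_accuracy(cm)))

  # equal class sizes make MAC equal accuracy
  eq <- as_confusion(matrix(c(8, 1, 1, 2, 6, 2, 3, 3, 4), 3, byrow = TRUE),
                     letters[1:3])
  expect_equal(as.numeric(mean_class_accuracy(eq)), accuracy(eq))

  # empty classes are excluded and reported
  m0 <- m; m0[2, ] <- 0L
  mac0 <- mean_class_accuracy(as_confusion(m0, cls))
  expect_equal(attr(mac0, "excluded"), "b")
  expect_error(ccr(as_confusion(m0, cls), "b"), "no reference")
  expect_equal(ccr(as_confusion(rbind(c(0, 5), c(0, 5)), c("x", "y")), "x"), 0)
})

test_that("Cohen's kappa equals its closed form and respects its bounds", {
  even <- as_confusion(matrix(c(25, 25, 25, 25), 2), c("x", "y"))
  expect_equal(cohens_kappa(even), 0)
  perfect <- as_confusion(diag(c(10L, 20L, 5L)), letters[1:3])
  expect_equal(cohens_kappa(perfect), 1)
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(sample(0:20, 9, replace = TRUE), 3)
    if (sum(m) == 0) next
    k <- cohens_kappa(as_confusion(m, letters[1:3]))
    expect_gte(k, -1); expect_lte(k, 1)
    if (sum(m) - sum(diag(m)) == 0) expect_equal(k, 1)
  }
})

test_that("exact McNemar p-values agree with binomial enumeration", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(1, 9)$p_value, 22 / 1024, tolerance = 1e-12)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  enum_p <- function(b, c) {
    n <- b + c
    probs <- choose(n, 0:n) / 2^n
    min(1, if (b == c) 1 else 2 * sum(probs[seq_len(min(b, c) + 1)]))
  }
  for (n in 1:20) for (b in 0:n) {
    expect_equal(mcnemar_test(b, n - b, mode = "exact")$p_value,
                 enum_p(b, n - b), tolerance = 1e-12,
                 label = sprintf("b=%d c=%d", b, n - b))
  }
  corr <- mcnemar_test(30, 10, mode = "corrected")
  expect_equal(corr$statistic, (abs(30 - 10) - 1)^2 / 40)
  expect_equal(mcnemar_test(30, 10)$mode, "corrected")   # b + c >= 25
  expect_equal(mcnemar_test(10, 10)$mode, "exact")
})

test_that("chi-square independence handles canonical matrices", {
  indep <- chi_square_independence(as_confusion(matrix(10, 2, 2), c("x", "y")))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p_value, 1)

  diag2 <- chi_square_independence(as_confusion(diag(c(20L, 20L)), c("x", "y")))
  expect_equal(diag2$statistic, 40)
  expect_equal(diag2$df, 1)

  m <- matrix(c(5, 0, 3, 0, 0, 0, 2, 0, 4), 3, byrow = TRUE)
  dropped <- chi_square_independence(as_confusion(m, letters[1:3]))
  expect_true("b" %in% dropped$dropped)
  expect_error(chi_square_independence(as_confusion(matrix(c(5, 5, 0, 0), 2,
                                                           byrow = TRUE),
                                                    c("x", "y"))),
               "fewer than 2")
})

test_that("agreement reports summarize paired readings", {
  cls <- c("p", "q", "r")
  labs <- sample(cls, 30, replace = TRUE)
  same <- agreement_report(labs, labs, cls)
  expect_equal(same$observed_agreement, 1)
  expect_equal(same$kappa, 1)

  a <- rep(c("p", "q"), 15)
  b <- rep(c("q", "p"), 15)
  expect_equal(agreement_report(a, b, cls)$observed_agreement, 0)
})

test_that("the packaged senior concordance fixture reproduces its margins", {
  cm <- senior_reader_concordance()
  expect_equal(cm$N, 589)
  expect_equal(unname(rowSums(cm$counts)), c(141, 134, 122, 114, 39, 31, 8))
  expect_equal(unname(colSums(cm$counts)), c(172, 142, 94, 99, 44, 31, 7))
  # full concordance on centromere, taking columns as the reference axis
  tcm <- as_confusion(t(cm$counts), cm$classes)
  expect_equal(ccr(tcm, "centromere"), 1.0)
  expect_lt(chi_square_independence(cm)$p_value, 0.05)
})

test_that("second-reader policies combine reader and CAD calls as stated", {
  cls <- hep2_patterns()
  set.seed(17)
  n <- 500
  gold <- sample(cls, n, replace = TRUE)
  corrupt <- function(p_correct) {
    ifelse(runif(n) < p_correct, gold, sample(cls, n, replace = TRUE))
  }
  reader <- corrupt(0.55)   # ~60% accuracy after accidental agreement
  cad <- corrupt(0.83)      # ~85% accuracy

  never <- reader_with_cad(reader, cad, gold, cls, policy = "never")
  expect_identical(never$assisted_labels, reader)
  expect_equal(never$delta$accuracy, 0)

  always <- reader_with_cad(reader, cad, gold, cls, policy = "always")
  cadm <- confusion_matrix(gold, cad, cls)
  expect_equal(always$after$accuracy, accuracy(cadm))

  conf <- reader_with_cad(reader, cad, gold, cls, policy = "confidence",
                          cad_confidence = rep(0.9, n), threshold = 0.5)
  expect_gte(conf$after$accuracy, conf$before$accuracy)
  expect_error(reader_with_cad(reader[-1], cad, gold, cls), "aligned")
})
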