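test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(train_intensity_classifier(x, rep("positive", 10)),
               "at least 2 classes")
  f <- matrix(rnorm(20 * 108), 20, 108,
              dimnames = list(NULL, hep2_feature_names()))
  expect_error(train_pattern_classifiers(f, rep("homogeneous", 20)),
               "missing training examples")
  expect_error(train_mitosis_classifiers(f, rep("interphase", 20)),
               "needs examples")
  expect_error(train_fusion(matrix(runif(18), 2, 9), rep("homogeneous", 2),
                            classifier_config(knn_grid = c(5L))),
               "fewer training points")
  expect_error(train_fusion(matrix(runif(40), 5, 8), rep("homogeneous", 5)),
               "9 score inputs")
})

test_that("the fusion K-NN matches a brute-force scan and breaks ties as stated", {
  set.seed(23)
  n <- 50
  x <- matrix(runif(n * 9), n, 9)
  y <- sample(hep2_patterns(), n, replace = TRUE)
  model <- train_fusion(x, y, classifier_config(tune = FALSE, knn_grid = 3L))
  expect_equal(model$k, 3)
  q <- matrix(runif(20 * 9), 20, 9)
  got <- predict_fusion(model, q)
  # independent brute-force K-NN with the same tie-break contract
  brute <- character(20)
  for (i in 1:20) {
    d <- numeric(n)
    for (j in 1:n) d[j] <- sqrt(sum((x[j, ] - q[i, ])^2))
    nn <- order(d)[1:3]
    tab <- table(y[nn])
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      ds <- sapply(cand, function(lb) sum(d[nn][y[nn] == lb]))
      cand <- cand[ds == min(ds)]
      cand <- cand[order(match(cand, hep2_patterns()))]
    }
    brute[i] <- cand[1]
  }
  expect_identical(unname(got), brute)

  # K = 1 returns the label of an exactly matching training point
  m1 <- train_fusion(x, y, classifier_config(tune = FALSE, knn_grid = 1L))
  expect_identical(unname(predict_fusion(m1, x[7, ])), y[7])

  # equidistant vote tie resolves to the earlier pattern-list label
  xt <- rbind(c(0, 0, 0, 0, 0, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0, 0, 0, 0))
  yt <- c("nucleolar", "homogeneous")
  # the query sits exactly between the two training points
  q0 <- c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0)
  expect_identical(unname(predict_fusion(structure(list(x = xt, y = yt, k = 2),
                                                   class = "hep2_fusion_model"),
                                         q0)),
                   "homogeneous")
})

test_that("a trained bundle emits nine bounded scores and enforces its schema", {
  bundle <- test_bundle()
  expect_length(bundle$pattern_models, 7)
  expect_identical(names(bundle$pattern_models), hep2_patterns())
  expect_length(bundle$mitosis_models, 2)

  cell <- generate_cell("centromere", "positive", radius = 15, seed = 303)
  ci <- cell_as_image(cell)
  feats <- extract_cell_features(ci$image, ci$region)
  s <- score_cell(feats, bundle)
  expect_length(s, 9)
  expect_all_finite(s)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(names(s), c(hep2_patterns(), hep2_mitosis_types()))
  expect_identical(s, score_cell(feats, bundle))
  expect_error(score_cell(feats[-1], bundle), "schema")
})

test_that("one-vs-all pattern classifiers rank their own class highest on average", {
  bundle <- test_bundle()
  own <- c(); other <- c()
  for (s in 1:10) {
    for (p in c("homogeneous", "nucleolar")) {
      ci <- cell_as_image(generate_cell(p, "positive", radius = 15, seed = 600 + s))
      sc <- score_cell(extract_cell_features(ci$image, ci$region), bundle)
      own <- c(own, sc[[p]])
      other <- c(other, mean(sc[setdiff(hep2_patterns(), p)]))
    }
  }
  expect_gt(mean(own), mean(other))
})

test_that("mitosis networks separate mitotic from interphase cells on average", {
  bundle <- test_bundle()
  pos_scores <- c(); inter_scores <- c()
  for (s in 1:10) {
    mc <- generate_mitotic_cell("positive_mitosis", "homogeneous", seed = 700 + s)
    reg <- region_from_mask(mc$mask)
    pos_scores <- c(pos_scores,
                    score_cell(extract_cell_features(mc$patch, reg),
                               bundle)[["positive_mitosis"]])
    ic <- cell_as_image(generate_cell("homogeneous", "positive", 15, seed = 800 + s))
    inter_scores <- c(inter_scores,
                      score_cell(extract_cell_features(ic$image, ic$region),
                                 bundle)[["positive_mitosis"]])
  }
  expect_gt(mean(pos_scores), mean(inter_scores))
})

test_that("negative images bypass the pattern stage entirely", {
  bundle <- test_bundle()
  neg <- generate_image(image_spec(256, 256, 6, 0, pattern = "homogeneous",
                                   intensity = "negative", seed = 41))
  bundle$counters$pattern_eval <- 0L
  rep <- classify_image(neg, bundle)
  if (rep$intensity == "negative") {
    expect_identical(rep$pattern, NA_character_)
    expect_equal(bundle$counters$pattern_eval, 0L)   # no pattern model invoked
  }
  pos <- generate_image(image_spec(256, 256, 6, 1, pattern = "centromere",
                                   intensity = "positive", seed = 42))
  rep2 <- classify_image(pos, bundle)
  expect_true(is.na(rep2$pattern) || rep2$pattern %in% hep2_patterns())
  expect_identical(rep2$pattern, classify_image(pos, bundle)$pattern)
})

test_that("well aggregation applies the majority and mitosis-discard rules", {
  bundle <- test_bundle()
  dir <- file.path(tempdir(), "well_rules")
  # a positive well whose three images contain no mitotic cell -> discarded
  cfg <- hep2_sim_config(n_mitotic = 0)
  paths <- character(3)
  for (k in 1:3) {
    spec <- image_spec(256, 256, 6, 0, pattern = "centromere",
                       intensity = "positive", seed = 900 + k)
    img <- generate_image(spec, cfg)
    dir.create(dir, showWarnings = FALSE)
    paths[k] <- file.path(dir, sprintf("nm_%d.png", k))
    png::writePNG(img$pixels / 255, paths[k])
  }
  w <- well_record("W_NOMITO", paths, intensity_label = "positive",
                   pattern_label = "centromere")
  rep <- classify_well(w, bundle)
  if (rep$intensity != "negative") {
    expect_true(rep$discarded)
    expect_identical(rep$discard_reason, "no mitosis detected")
  }

  # a negative 1-image well is never subject to the discard rule
  negimg <- generate_image(image_spec(256, 256, 6, 0, intensity = "negative",
                                      seed = 950))
  npath <- file.path(dir, "neg.png")
  png::writePNG(negimg$pixels / 255, npath)
  nrep <- classify_well(well_record("W_NEG", npath,
                                    intensity_label = "negative"), bundle)
  if (nrep$intensity == "negative") {
    expect_false(nrep$discarded)
    expect_identical(nrep$pattern, NA_character_)
  }

  expect_error(well_record("W_BAD", paths, intensity_label = "negative"),
               "exactly 1 image")
})

test_that("bundles round-trip through save/load with identical predictions", {
  bundle <- test_bundle()
  dir <- file.path(tempdir(), "bundle_rt")
  save_model_bundle(bundle, dir)
  restored <- load_model_bundle(dir)
  probe <- lapply(1:5, function(s) {
    ci <- cell_as_image(generate_cell(hep2_patterns()[s], "positive", 15,
                                      seed = 1000 + s))
    extract_cell_features(ci$image, ci$region)
  })
  for (f in probe) {
    expect_equal(score_cell(f, restored), score_cell(f, bundle))
    expect_identical(predict_fusion(restored$fusion_model, score_cell(f, restored)),
                     predict_fusion(bundle$fusion_model, score_cell(f, bundle)))
  }
  expect_error(load_model_bundle(file.path(tempdir(), "nope_dir")),
               "not a model bundle")
})
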