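#' Classifier configuration
#'
#' Hyperparameters of the CAD pipeline. All stochastic training (network
#' initialisation, cross-validation folds, tuning subsamples) derives from
#' `seed`, so a trained bundle is a pure function of data and configuration.
#'
#' @param seed Global training seed.
#' @param tune Tune SVM cost and the fusion K by cross-validated mean class
#'   accuracy (MAC); with `FALSE` the first grid values are used.
#' @param cv_folds Stratified cross-validation folds used while tuning.
#' @param cost_grid Candidate SVM cost values.
#' @param tune_subsample Maximum rows used during tuning (the final model is
#'   always fitted on all rows).
#' @param nn_size,nn_decay,nn_maxit Mitosis network: hidden width, weight
#'   decay, iteration cap.
#' @param knn_grid Candidate odd K values for the fusion stage.
#' @param mitosis_threshold Score above which a cell counts as mitotic when
#'   deciding image-level mitosis presence.
#' @param max_cells_per_image Cap on segmented cells harvested per image for
#'   training.
#' @param reject_floor Optional confidence floor; below it the fused call
#'   becomes `"other"`. `NULL` (default) disables rejection.
#' @return A list of classifier parameters.
#' @export
classifier_config <- function(seed = 42L, tune = TRUE, cv_folds = 3L,
                              cost_grid = c(1, 10), tune_subsample = 600L,
                              nn_size = 16L, nn_decay = 0.1, nn_maxit = 150L,
                              knn_grid = c(3L, 5L, 7L, 9L),
                              mitosis_threshold = 0.5,
                              max_cells_per_image = 5L,
                              reject_floor = NULL) {
  stopifnot(all(knn_grid %% 2 == 1))
  list(seed = as.integer(seed), tune = tune, cv_folds = as.integer(cv_folds),
       cost_grid = cost_grid, tune_subsample = as.integer(tune_subsample),
       nn_size = as.integer(nn_size), nn_decay = nn_decay,
       nn_maxit = as.integer(nn_maxit), knn_grid = as.integer(knn_grid),
       mitosis_threshold = mitosis_threshold,
       max_cells_per_image = as.integer(max_cells_per_image),
       reject_floor = reject_floor)
}

# ---- feature standardization --------------------------------------------

fit_scaling <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(center = mu, scale = sd)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

# Stratified fold assignment, deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Binary SVM with standardized features; score is the logistic squash of the
# decision value so it lives in [0, 1].
fit_margin_classifier <- function(x, y, cost) {
  sc <- fit_scaling(x)
  xs <- apply_scaling(x, sc)
  yf <- factor(y, levels = c(FALSE, TRUE))
  wts <- 1 / table(yf)
  wts <- wts / sum(wts) * 2
  fit <- e1071::svm(xs, yf, kernel = "radial", cost = cost, scale = FALSE,
                    class.weights = wts)
  # the sign convention of the decision value depends on which class e1071
  # saw first; record whether it points toward TRUE
  dvn <- colnames(attr(stats::predict(fit, xs[1, , drop = FALSE],
                                      decision.values = TRUE),
                       "decision.values"))
  list(fit = fit, scaling = sc, flip = !startsWith(dvn, "TRUE"))
}

margin_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  xs <- apply_scaling(x, model$scaling)
  dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (model$flip) dv <- -dv
  1 / (1 + exp(-dv))
}

# Cross-validated cost selection for a binary margin classifier, figure of
# merit = MAC of the two classes (balanced accuracy).
tune_margin_cost <- function(x, y, config) {
  if (!config$tune || length(config$cost_grid) == 1) return(config$cost_grid[1])
  n <- nrow(x)
  idx <- seq_len(n)
  if (n > config$tune_subsample) {
    idx <- with_seed(config$seed, sample.int(n, config$tune_subsample))
  }
  xs <- x[idx, , drop = FALSE]; ys <- y[idx]
  if (length(unique(ys)) < 2) return(config$cost_grid[1])
  fold <- stratified_folds(as.character(ys), config$cv_folds, config$seed + 1L)
  macs <- vapply(config$cost_grid, function(cost) {
    accs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (length(unique(ys[tr])) < 2 || !any(te)) return(NA_real_)
      m <- fit_margin_classifier(xs[tr, , drop = FALSE], ys[tr], cost)
      pred <- margin_score(m, xs[te, , drop = FALSE]) > 0.5
      mean(c(mean(pred[ys[te]]), mean(!pred[!ys[te]])), na.rm = TRUE)
    }, 0)
    mean(accs, na.rm = TRUE)
  }, 0)
  config$cost_grid[which.max(macs)]
}

# ---- intensity triage ----------------------------------------------------

#' Summarize one image for intensity triage
#'
#' Image-level descriptor: global green-channel statistics plus the
#' per-feature mean of the segmented cells' descriptors (zeros when no cell
#' was segmented).
#'
#' @param image RGB array, matrix or `hep2_synthetic_image`.
#' @param cell_features Matrix of per-cell descriptors (may have 0 rows).
#' @return Named numeric vector.
#' @export
summarize_image <- function(image, cell_features) {
  g <- as_green_matrix(image)
  qs <- stats::quantile(g, c(0.5, 0.75, 0.9, 0.99), names = FALSE)
  glob <- c(g.mean = mean(g), g.sd = stats::sd(g), g.median = qs[1],
            g.q75 = qs[2], g.q90 = qs[3], g.q99 = qs[4],
            g.frac48 = mean(g > 48), g.frac112 = mean(g > 112),
            n.cells = nrow(cell_features))
  cellmean <- if (nrow(cell_features) > 0) colMeans(cell_features) else
    stats::setNames(numeric(length(hep2_feature_names())), hep2_feature_names())
  names(cellmean) <- paste0("cellmean.", names(cellmean))
  c(glob, cellmean)
}

#' Train the intensity triage cascade
#'
#' Two margin (SVM) classifiers in cascade: negative vs nonnegative, then
#' intermediate vs positive, on image-level summary vectors. The SVM cost is
#' selected by stratified cross-validation maximizing mean class accuracy.
#'
#' @param summaries Numeric matrix, one row per image ([summarize_image()]).
#' @param labels Intensity class per image.
#' @param config See [classifier_config()].
#' @return An intensity model usable with [predict_intensity()].
#' @export
train_intensity_classifier <- function(summaries, labels, config = classifier_config()) {
  labels <- vapply(labels, assert_intensity, "")
  if (length(unique(labels)) < 2) {
    stop("intensity training needs at least 2 classes; got only '",
         unique(labels), "'")
  }
  y1 <- labels != "negative"
  cost1 <- tune_margin_cost(summaries, y1, config)
  m1 <- fit_margin_classifier(summaries, y1, cost1)
  sub <- labels != "negative"
  m2 <- NULL; cost2 <- NA
  if (length(unique(labels[sub])) == 2) {
    y2 <- labels[sub] == "positive"
    cost2 <- tune_margin_cost(summaries[sub, , drop = FALSE], y2, config)
    m2 <- fit_margin_classifier(summaries[sub, , drop = FALSE], y2, cost2)
  }
  structure(list(stage1 = m1, stage2 = m2, cost = c(cost1, cost2),
                 schema = colnames(summaries)),
            class = "hep2_intensity_model")
}

#' @rdname train_intensity_classifier
#' @param model A trained intensity model.
#' @export
predict_intensity <- function(model, summaries) {
  if (is.null(dim(summaries))) summaries <- matrix(summaries, 1,
                                                   dimnames = list(NULL, names(summaries)))
  s1 <- margin_score(model$stage1, summaries) > 0.5
  out <- rep("negative", nrow(summaries))
  if (any(s1)) {
    if (is.null(model$stage2)) {
      out[s1] <- "positive"
    } else {
      s2 <- margin_score(model$stage2, summaries[s1, , drop = FALSE]) > 0.5
      out[s1] <- ifelse(s2, "positive", "intermediate")
    }
  }
  out
}

# ---- pattern and mitosis classifiers ------------------------------------

#' Train the seven one-vs-all pattern classifiers
#'
#' One binary margin classifier per staining pattern, each trained to
#' discriminate its class from all others and emitting a score in \[0, 1\].
#' Feature standardization is fitted per classifier on training data only.
#'
#' @param features Numeric matrix, one row per cell (108 columns).
#' @param labels Staining pattern per cell.
#' @param config See [classifier_config()].
#' @return A named list of 7 models, in pattern-list order.
#' @export
train_pattern_classifiers <- function(features, labels, config = classifier_config()) {
  labels <- vapply(labels, assert_pattern, "")
  absent <- setdiff(hep2_patterns(), unique(labels))
  if (length(absent) > 0) {
    stop("missing training examples for pattern(s): ",
         paste(absent, collapse = ", "))
  }
  models <- lapply(hep2_patterns(), function(p) {
    y <- labels == p
    cost <- tune_margin_cost(features, y, config)
    m <- fit_margin_classifier(features, y, cost)
    m$pattern <- p
    m
  })
  names(models) <- hep2_patterns()
  models
}

#' Train the two mitosis classifiers
#'
#' Two small feed-forward networks (one hidden layer): positive-mitosis vs
#' rest and negative-mitosis vs rest, over standardized cell descriptors.
#' Initialisation is seeded, so training is deterministic.
#'
#' @param features Numeric matrix of cell descriptors.
#' @param labels One of `positive_mitosis`, `negative_mitosis`,
#'   `interphase` per cell.
#' @param config See [classifier_config()].
#' @return Named list of 2 models (`positive_mitosis`, `negative_mitosis`).
#' @export
train_mitosis_classifiers <- function(features, labels, config = classifier_config()) {
  ok <- c(hep2_mitosis_types(), "interphase")
  bad <- setdiff(unique(labels), ok)
  if (length(bad)) stop("unknown mitosis label(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(ok, unique(labels))
  if (length(missing)) {
    stop("mitosis training needs examples of: ", paste(missing, collapse = ", "))
  }
  sc <- fit_scaling(features)
  xs <- apply_scaling(features, sc)
  models <- lapply(seq_along(hep2_mitosis_types()), function(i) {
    ty <- hep2_mitosis_types()[i]
    y <- as.numeric(labels == ty)
    fit <- with_seed(config$seed + i, {
      nnet::nnet(xs, y, size = config$nn_size, decay = config$nn_decay,
                 maxit = config$nn_maxit, MaxNWts = 5000, trace = FALSE)
    })
    list(fit = fit, scaling = sc, type = ty)
  })
  names(models) <- hep2_mitosis_types()
  models
}

nn_score <- function(model, x) {
  as.numeric(stats::predict(model$fit, apply_scaling(x, model$scaling)))
}

# ---- fusion --------------------------------------------------------------

#' Train the K-NN fusion stage
#'
#' K-nearest-neighbour classifier over the 9-dimensional score space (seven
#' pattern scores plus two mitosis scores). K is odd, selected from
#' `config$knn_grid` by cross-validated mean class accuracy. Euclidean
#' metric; vote ties are broken by the smallest summed neighbour distance,
#' then by pattern-list order.
#'
#' @param scores Numeric matrix with 9 columns, one row per training cell.
#' @param labels Staining pattern per row.
#' @param config See [classifier_config()].
#' @return A fusion model usable with [predict_fusion()].
#' @export
train_fusion <- function(scores, labels, config = classifier_config()) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 9) stop("fusion consumes exactly 9 score inputs, got ", ncol(scores))
  labels <- vapply(labels, assert_pattern, "")
  grid <- config$knn_grid[config$knn_grid <= nrow(scores)]
  if (length(grid) == 0) {
    stop("fewer training points (", nrow(scores), ") than the smallest K (",
         min(config$knn_grid), ")")
  }
  k_best <- grid[1]
  if (config$tune && length(grid) > 1) {
    fold <- stratified_folds(labels, config$cv_folds, config$seed + 7L)
    macs <- vapply(grid, function(k) {
      rates <- c()
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f
        if (sum(tr) < k) next
        pred <- knn_predict(scores[tr, , drop = FALSE], labels[tr],
                            scores[!tr, , drop = FALSE], k)
        for (p in unique(labels[!tr])) {
          rates <- c(rates, mean(pred[labels[!tr] == p] == p))
        }
      }
      mean(rates)
    }, 0)
    k_best <- grid[which.max(macs)]
  }
  structure(list(x = scores, y = labels, k = k_best),
            class = "hep2_fusion_model")
}

# Brute K-NN with the documented tie-breaks.
knn_predict <- function(train_x, train_y, query_x, k) {
  if (is.null(dim(query_x))) query_x <- matrix(query_x, 1)
  apply(query_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(lb) sum(d[nn][train_y[nn] == lb]), 0)
      top <- top[sums == min(sums)]
      if (length(top) > 1) top <- top[order(match(top, hep2_patterns()))]
    }
    top[1]
  })
}

#' @rdname train_fusion
#' @param model A trained fusion model.
#' @param scores Matrix (or single vector) of 9-score rows to classify.
#' @export
predict_fusion <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1)
  if (ncol(scores) != 9) stop("fusion consumes exactly 9 score inputs, got ", ncol(scores))
  knn_predict(model$x, model$y, scores, model$k)
}

# ---- bundle --------------------------------------------------------------

#' Score one cell with a trained bundle
#'
#' Runs the seven one-vs-all pattern classifiers and the two mitosis
#' networks on a 108-value descriptor, returning the nine fusion inputs in
#' canonical order (patterns in pattern-list order, then positive and
#' negative mitosis).
#'
#' @param features Named numeric vector of length 108.
#' @param bundle A trained [train_cad()] bundle.
#' @return Named numeric vector of 9 scores in \[0, 1\].
#' @export
score_cell <- function(features, bundle) {
  x <- check_feature_schema(features, bundle)
  bundle$counters$pattern_eval <- bundle$counters$pattern_eval + 1L
  ps <- vapply(bundle$pattern_models, function(m) margin_score(m, x), 0)
  ms <- vapply(bundle$mitosis_models, function(m) min(1, max(0, nn_score(m, x))), 0)
  stats::setNames(c(ps, ms), c(hep2_patterns(), hep2_mitosis_types()))
}

check_feature_schema <- function(features, bundle) {
  if (is.matrix(features)) {
    if (ncol(features) != length(bundle$feature_schema)) {
      stop("feature schema mismatch: expected ", length(bundle$feature_schema),
           " features, got ", ncol(features))
    }
    return(features)
  }
  if (length(features) != length(bundle$feature_schema)) {
    stop("feature schema mismatch: expected ", length(bundle$feature_schema),
         " features, got ", length(features))
  }
  matrix(features, 1, dimnames = list(NULL, names(features)))
}

#' Train the full CAD bundle from a dataset manifest
#'
#' Reads a labeled dataset (see [generate_dataset()]), segments every image,
#' labels segmented cells by matching them against the ground-truth
#' sidecars (mitotic cells) and the well pattern (interphase cells), and
#' trains the four stages: the intensity cascade, the seven one-vs-all
#' pattern classifiers, the two mitosis networks, and the K-NN fusion.
#'
#' @param manifest_path Path to a `manifest.csv`.
#' @param config See [classifier_config()].
#' @param seg_config See [segmentation_config()].
#' @param verbose Print per-stage progress.
#' @return An object of class `hep2_model_bundle`.
#' @export
train_cad <- function(manifest_path, config = classifier_config(),
                      seg_config = segmentation_config(), verbose = FALSE) {
  wells <- read_manifest(manifest_path)
  if (any(vapply(wells, function(w) is.na(w$intensity_label), TRUE))) {
    bad <- names(wells)[vapply(wells, function(w) is.na(w$intensity_label), TRUE)]
    stop("wells lack intensity labels: ", paste(bad, collapse = ", "))
  }
  harvest <- harvest_training_data(wells, config, seg_config, verbose)
  if (verbose) message("training intensity cascade ...")
  intensity_model <- train_intensity_classifier(harvest$summaries,
                                                harvest$summary_labels, config)
  if (verbose) message("training pattern classifiers ...")
  pat_idx <- harvest$cell_labels %in% hep2_patterns()
  pattern_models <- train_pattern_classifiers(
    harvest$cell_features[pat_idx, , drop = FALSE],
    harvest$cell_labels[pat_idx], config)
  if (verbose) message("training mitosis networks ...")
  mito_labels <- ifelse(harvest$cell_labels %in% hep2_mitosis_types(),
                        harvest$cell_labels, "interphase")
  mitosis_models <- train_mitosis_classifiers(harvest$cell_features,
                                              mito_labels, config)
  bundle <- structure(list(
    intensity_model = intensity_model,
    pattern_models = pattern_models,
    mitosis_models = mitosis_models,
    fusion_model = NULL,
    feature_schema = hep2_feature_names(),
    config = config,
    metadata = list(schema_version = 1L, seed = config$seed,
                    n_train_wells = length(wells),
                    n_train_cells = nrow(harvest$cell_features)),
    counters = new.env(parent = emptyenv())),
    class = "hep2_model_bundle")
  bundle$counters$pattern_eval <- 0L
  if (verbose) message("training fusion stage ...")
  xs <- harvest$cell_features[pat_idx, , drop = FALSE]
  sc <- t(apply(xs, 1, function(v) {
    score_cell(stats::setNames(v, hep2_feature_names()), bundle)
  }))
  bundle$fusion_model <- train_fusion(sc, harvest$cell_labels[pat_idx], config)
  bundle$counters$pattern_eval <- 0L
  bundle
}

# Segment + featurize every image of a well list; label cells from sidecar
# truth (mitosis) and the well's pattern label (interphase).
harvest_training_data <- function(wells, config, seg_config, verbose = FALSE) {
  summaries <- list(); summary_labels <- character()
  cell_features <- list(); cell_labels <- character()
  for (w in wells) {
    for (path in w$images) {
      img <- read_image(path)
      regions <- segment_cells(img, seg_config)
      feats <- if (length(regions)) {
        t(vapply(regions, function(r) extract_cell_features(img, r),
                 numeric(length(hep2_feature_names()))))
      } else matrix(numeric(0), 0, length(hep2_feature_names()),
                    dimnames = list(NULL, hep2_feature_names()))
      summaries[[length(summaries) + 1]] <- summarize_image(img, feats)
      summary_labels <- c(summary_labels, w$intensity_label)
      if (w$intensity_label == "negative" || length(regions) == 0) next
      sidecar <- sub("[.][A-Za-z]+$", ".json", path)
      truth <- if (file.exists(sidecar)) read_truth_sidecar(sidecar) else list()
      lab <- rep(w$pattern_label, length(regions))
      if (length(truth)) {
        mm <- match_regions(regions, truth)
        if (nrow(mm$pairs)) {
          for (r in seq_len(nrow(mm$pairs))) {
            tmito <- truth[[mm$pairs[r, "truth"]]]$mitosis
            if (!is.na(tmito)) lab[mm$pairs[r, "predicted"]] <- tmito
          }
        }
      }
      keep <- seq_len(min(length(regions), config$max_cells_per_image))
      # always retain mitotic cells: they are rare and both types are needed
      keep <- union(keep, which(lab %in% hep2_mitosis_types()))
      cell_features[[length(cell_features) + 1]] <- feats[keep, , drop = FALSE]
      cell_labels <- c(cell_labels, lab[keep])
    }
  }
  list(summaries = do.call(rbind, summaries), summary_labels = summary_labels,
       cell_features = do.call(rbind, cell_features), cell_labels = cell_labels)
}

#' @export
print.hep2_model_bundle <- function(x, ...) {
  cat(sprintf(paste0("HEp-2 CAD bundle (schema v%d): intensity cascade + %d ",
                     "pattern classifiers + %d mitosis networks + K-NN fusion ",
                     "(K=%s), trained on %d cells\n"),
              x$metadata$schema_version, length(x$pattern_models),
              length(x$mitosis_models),
              if (is.null(x$fusion_model)) "?" else x$fusion_model$k,
              x$metadata$n_train_cells))
  invisible(x)
}

#' Save / load a model bundle
#'
#' A bundle serializes to a directory holding a JSON metadata file (schema
#' version, training configuration, seed) and one RDS blob per component.
#'
#' @param bundle A trained bundle.
#' @param dir Directory path.
#' @return `dir` (save) or the restored bundle (load).
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- bundle$metadata
  meta$config <- bundle$config[!vapply(bundle$config, is.null, TRUE)]
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (part in c("intensity_model", "pattern_models", "mitosis_models",
                 "fusion_model")) {
    saveRDS(bundle[[part]], file.path(dir, paste0(part, ".rds")))
  }
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("not a model bundle directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L) {
    stop("unsupported bundle schema version: ", meta$schema_version)
  }
  config <- do.call(classifier_config, meta$config[names(meta$config) %in%
                                                     names(formals(classifier_config))])
  bundle <- structure(list(
    intensity_model = readRDS(file.path(dir, "intensity_model.rds")),
    pattern_models = readRDS(file.path(dir, "pattern_models.rds")),
    mitosis_models = readRDS(file.path(dir, "mitosis_models.rds")),
    fusion_model = readRDS(file.path(dir, "fusion_model.rds")),
    feature_schema = hep2_feature_names(),
    config = config,
    metadata = meta[setdiff(names(meta), "config")],
    counters = new.env(parent = emptyenv())),
    class = "hep2_model_bundle")
  bundle$counters$pattern_eval <- 0L
  bundle
}

# ---- image / well classification ----------------------------------------

#' Classify one image
#'
#' Reproduces the reading flow: intensity triage first; staining-pattern
#' analysis runs only for nonnegative images. Every segmented cell is scored
#' by the nine classifiers and fused; the image pattern is the majority over
#' the fused labels of non-mitotic cells (ties broken by the highest mean
#' fused-class score); mitosis presence is declared when any cell's maximum
#' mitosis score exceeds the configured threshold.
#'
#' @param image RGB array, path to a PNG, or `hep2_synthetic_image`.
#' @param bundle Trained bundle.
#' @param seg_config See [segmentation_config()].
#' @return An `hep2_image_report`: intensity, pattern (`NA` for negative or
#'   unanalyzable images), `has_mitosis`, `n_cells`, `per_cell_scores`,
#'   `unanalyzable`.
#' @export
classify_image <- function(image, bundle, seg_config = segmentation_config()) {
  if (is.character(image)) image <- read_image(image)
  regions <- segment_cells(image, seg_config)
  feats <- if (length(regions)) {
    t(vapply(regions, function(r) extract_cell_features(image, r),
             numeric(length(bundle$feature_schema))))
  } else matrix(numeric(0), 0, length(bundle$feature_schema),
                dimnames = list(NULL, bundle$feature_schema))
  intensity <- predict_intensity(bundle$intensity_model,
                                 summarize_image(image, feats))
  rep0 <- structure(list(intensity = intensity, pattern = NA_character_,
                         has_mitosis = FALSE, n_cells = length(regions),
                         per_cell_scores = list(), unanalyzable = FALSE),
                    class = "hep2_image_report")
  if (intensity == "negative") return(rep0)
  if (length(regions) == 0) { rep0$unanalyzable <- TRUE; return(rep0) }
  scores <- lapply(seq_len(nrow(feats)), function(i) score_cell(feats[i, ], bundle))
  smat <- do.call(rbind, scores)
  mito_max <- apply(smat[, hep2_mitosis_types(), drop = FALSE], 1, max)
  is_mito <- mito_max > bundle$config$mitosis_threshold
  rep0$has_mitosis <- any(is_mito)
  use <- if (all(is_mito)) seq_len(nrow(smat)) else which(!is_mito)
  fused <- predict_fusion(bundle$fusion_model, smat[use, , drop = FALSE])
  if (!is.null(bundle$config$reject_floor)) {
    conf <- apply(smat[use, hep2_patterns(), drop = FALSE], 1, max)
    fused[conf < bundle$config$reject_floor] <- "other"
  }
  votes <- table(fused)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    meansc <- vapply(top, function(p) {
      if (p == "other") return(-Inf)
      mean(smat[use, p])
    }, 0)
    top <- top[which.max(meansc)]
  }
  rep0$pattern <- top[1]
  rep0$per_cell_scores <- scores
  rep0
}

#' Classify one well
#'
#' Applies [classify_image()] to each image of the well, then aggregates:
#' intensity is the majority over image intensities (ties resolved toward
#' the more positive class); the pattern is the majority over the patterns
#' of nonnegative images; the well is discarded — with reason
#' `"no mitosis detected"` — when it is nonnegative and no image contains a
#' detected mitotic cell.
#'
#' @param well A [well_record()] (image paths) or a list of in-memory images
#'   plus a `well_id`.
#' @param bundle Trained bundle.
#' @param seg_config See [segmentation_config()].
#' @return An `hep2_well_report`.
#' @export
classify_well <- function(well, bundle, seg_config = segmentation_config()) {
  stopifnot(inherits(well, "hep2_well_record"))
  reports <- lapply(well$images, classify_image, bundle = bundle,
                    seg_config = seg_config)
  ints <- vapply(reports, `[[`, "", "intensity")
  tallies <- table(factor(ints, levels = hep2_intensities()))
  top <- names(tallies)[tallies == max(tallies)]
  intensity <- top[which.max(match(top, hep2_intensities()))]
  pats <- unlist(lapply(reports, function(r) {
    if (!is.na(r$pattern) && r$intensity != "negative") r$pattern else NULL
  }))
  pattern <- NA_character_
  if (intensity != "negative" && length(pats)) {
    pv <- table(pats)
    cand <- names(pv)[pv == max(pv)]
    pattern <- cand[order(match(cand, hep2_patterns()))][1]
  }
  discarded <- intensity != "negative" && !any(vapply(reports, `[[`, TRUE, "has_mitosis"))
  structure(list(well_id = well$well_id, intensity = intensity,
                 pattern = pattern, discarded = discarded,
                 discard_reason = if (discarded) "no mitosis detected" else NA_character_,
                 image_reports = reports),
            class = "hep2_well_report")
}

#' @export
print.hep2_well_report <- function(x, ...) {
  cat(sprintf("well %s: intensity %s, pattern %s%s\n", x$well_id, x$intensity,
              if (is.na(x$pattern)) "-" else x$pattern,
              if (x$discarded) sprintf(" [DISCARDED: %s]", x$discard_reason) else ""))
  invisible(x)
}

#' Write well reports
#'
#' One JSON per well plus a flat CSV summary
#' (`well_id, intensity, pattern, discarded`).
#'
#' @param reports List of `hep2_well_report`.
#' @param dir Output directory.
#' @return The summary data.frame, invisibly.
#' @export
write_well_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in reports) {
    slim <- r
    slim$image_reports <- lapply(r$image_reports, function(ir) {
      ir$per_cell_scores <- lapply(ir$per_cell_scores, function(s) round(s, 6))
      unclass(ir)
    })
    jsonlite::write_json(unclass(slim),
                         file.path(dir, paste0(r$well_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  summary <- data.frame(
    well_id = vapply(reports, `[[`, "", "well_id"),
    intensity = vapply(reports, `[[`, "", "intensity"),
    pattern = vapply(reports, `[[`, "", "pattern"),
    discarded = vapply(reports, `[[`, TRUE, "discarded"),
    stringsAsFactors = FALSE)
  utils::write.csv(summary, file.path(dir, "well_summary.csv"), row.names = FALSE)
  invisible(summary)
}
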