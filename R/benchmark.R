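#' Synthetic end-to-end benchmark
#'
#' Generates a labeled training set and a disjoint test set with the
#' synthetic simulator, trains the full CAD bundle on the first and
#' classifies the wells of the second, then scores well-level pattern mean
#' class accuracy and intensity accuracy against the simulator's ground
#' truth. Wells whose predicted pattern is missing (triaged negative or
#' unanalyzable) count as misclassified. This is the package's standing
#' check that the whole pipeline — simulation, segmentation, features, the
#' nine classifiers and the fusion stage — recovers the generating classes.
#'
#' @param wells_per_class Training wells per staining pattern (default 30).
#' @param test_wells_per_class Test wells per staining pattern (default 10).
#' @param train_seed,test_seed Dataset seeds (defaults 7 and 8).
#' @param negative_fraction Negative-well fraction in both sets.
#' @param dir Working directory for the generated datasets and reports.
#' @param sim_config,cls_config,seg_config Module configurations.
#' @param verbose Print stage progress.
#' @return List with `pattern_mac`, `intensity_accuracy`, `per_pattern_ccr`,
#'   `n_test_wells`, `n_discarded`, `fusion_k`, and the `bundle`.
#' @export
hep2_benchmark <- function(wells_per_class = 30L, test_wells_per_class = 10L,
                           train_seed = 7L, test_seed = 8L,
                           negative_fraction = 0.10,
                           dir = file.path(tempdir(), "hep2_benchmark"),
                           sim_config = hep2_sim_config(),
                           cls_config = classifier_config(),
                           seg_config = segmentation_config(),
                           verbose = FALSE) {
  req <- stats::setNames(rep(wells_per_class, 7), hep2_patterns())
  req_test <- stats::setNames(rep(test_wells_per_class, 7), hep2_patterns())
  train_dir <- file.path(dir, "train"); test_dir <- file.path(dir, "test")
  if (verbose) message("simulating training set ...")
  generate_dataset(req, negative_fraction, train_seed, train_dir, sim_config)
  if (verbose) message("simulating test set ...")
  generate_dataset(req_test, negative_fraction, test_seed, test_dir, sim_config)
  if (verbose) message("training bundle ...")
  bundle <- train_cad(file.path(train_dir, "manifest.csv"), cls_config,
                      seg_config, verbose = verbose)
  if (verbose) message("classifying test wells ...")
  wells <- read_manifest(file.path(test_dir, "manifest.csv"))
  reports <- lapply(wells, classify_well, bundle = bundle,
                    seg_config = seg_config)
  ref_int <- vapply(wells, `[[`, "", "intensity_label")
  pred_int <- vapply(reports, `[[`, "", "intensity")
  intensity_accuracy <- mean(pred_int == ref_int)
  ref_pat <- vapply(wells, function(w) {
    if (is.na(w$pattern_label)) NA_character_ else w$pattern_label
  }, "")
  pred_pat <- vapply(reports, `[[`, "", "pattern")
  pos <- !is.na(ref_pat)
  per_pattern <- vapply(hep2_patterns(), function(p) {
    idx <- pos & ref_pat == p
    mean(!is.na(pred_pat[idx]) & pred_pat[idx] == p)
  }, 0)
  list(pattern_mac = mean(per_pattern),
       intensity_accuracy = intensity_accuracy,
       per_pattern_ccr = per_pattern,
       n_test_wells = length(wells),
       n_discarded = sum(vapply(reports, `[[`, TRUE, "discarded")),
       fusion_k = bundle$fusion_model$k,
       bundle = bundle)
}
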