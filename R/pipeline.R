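#' Preprocess an annotated recording into labeled feature tensors
#'
#' The real-data path: conform to the 19-channel montage at 250 Hz, cut
#' 12-s windows, remove eye components per window (ICA + fronto-polar
#' Pearson screen), then STFT-featurize. Set `ica_scope = "recording"` to
#' run ICA once on the whole recording instead of per window (faster on
#' long files).
#'
#' @param rec An [eeg_recording()] (e.g. from [read_edf()]).
#' @param window_s Window length in seconds.
#' @param label_rule Overlap fraction for seizure labeling (0 = any
#'   overlap); see [segment_recording()].
#' @param ica_clean Remove eye components before featurization.
#' @param eye_threshold Rejection threshold on the fronto-polar Pearson
#'   score.
#' @param ica_scope `"window"` (per 12-s segment) or `"recording"`.
#' @param stft An [stft_config()].
#' @param pool Optional [pool_features()] argument list.
#' @param seed Seed for the ICA initialization.
#' @return A list of class `eeg_dataset` (see [make_dataset()]).
#' @export
preprocess_recording <- function(rec, window_s = 12, label_rule = 0,
                                 ica_clean = TRUE, eye_threshold = 0.8,
                                 ica_scope = c("window", "recording"),
                                 stft = stft_config(), pool = NULL,
                                 seed = 1L) {
  ica_scope <- match.arg(ica_scope)
  rec <- conform_recording(rec)
  if (ica_clean && ica_scope == "recording") {
    rec <- clean_eye_artifacts(rec, threshold = eye_threshold, seed = seed)
  }
  seg <- segment_recording(rec, window_s = window_s, label_rule = label_rule)
  n <- length(seg$segments)
  features <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seg$segments[[i]]
    if (ica_clean && ica_scope == "window") {
      wrec <- eeg_recording(s, rec$fs, rec$channel_names)
      wrec <- clean_eye_artifacts(wrec, threshold = eye_threshold,
                                  seed = derive_seed(seed, i))
      s <- wrec$signals
    }
    fx <- stft_features(s, stft)
    if (!is.null(pool)) fx <- do.call(pool_features, c(list(fx), pool))
    features[[i]] <- fx
  }
  manifest <- list(
    source = rec$id, window_s = window_s, label_rule = label_rule,
    ica_clean = ica_clean, eye_threshold = eye_threshold,
    ica_scope = ica_scope, stft = unclass(stft), pool = pool, seed = seed,
    flatten_order = "channel-major, then frame, then frequency (frequency fastest)"
  )
  structure(
    list(x = if (n) flatten_features(features) else
           matrix(0, 0, 0),
         features = features, labels = seg$labels,
         y = as.integer(seg$labels == "seizure"),
         onsets_s = seg$onsets_s, manifest = manifest),
    class = "eeg_dataset"
  )
}

#' Write / read a feature-set directory
#'
#' Layout: `manifest.yaml` (configuration and provenance, human-readable),
#' `labels.csv`, and one serialized array container per split
#' (`features_<split>.rds`). Stable across runs given identical inputs.
#'
#' @param splits Named list of `list(x, y)` splits (e.g. from
#'   [assemble_splits()]), or a single `eeg_dataset`.
#' @param dir Target directory.
#' @param manifest Manifest list to record.
#' @return `dir`, invisibly.
#' @export
write_feature_set <- function(splits, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(splits, "eeg_dataset")) {
    manifest <- if (is.null(manifest)) splits$manifest else manifest
    splits <- list(all = list(x = splits$x, y = splits$y))
  }
  splits <- splits[intersect(c("train", "val", "test", "all"),
                             names(splits))]
  lab <- do.call(rbind, lapply(names(splits), function(nm) {
    data.frame(split = nm, index = seq_along(splits[[nm]]$y),
               label = ifelse(splits[[nm]]$y == 1L, "seizure", "background"))
  }))
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  for (nm in names(splits)) {
    saveRDS(splits[[nm]]$x, file.path(dir, sprintf("features_%s.rds", nm)),
            compress = FALSE)
  }
  yaml::write_yaml(c(list(splits = names(splits)), manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  splits <- lapply(manifest$splits, function(nm) {
    list(x = readRDS(file.path(dir, sprintf("features_%s.rds", nm))),
         y = as.integer(lab$label[lab$split == nm] == "seizure"))
  })
  names(splits) <- manifest$splits
  c(splits, list(manifest = manifest))
}

#' Evaluate fixed trained weights on another dataset
#'
#' Cross-dataset (out-of-sample) evaluation: the feature standardization
#' statistics saved from the training split and the selected weights are
#' applied as-is — nothing is refit.
#'
#' @param fit A `kan_fit` from [train_kan()].
#' @param x,y Feature matrix (unstandardized) and labels of the other
#'   dataset.
#' @param stats The [feature_stats()] of the training split.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return An `eval_report` (one-row tibble) with the provenance of the
#'   stats attached as attribute `"stats_provenance"`.
#' @export
cross_dataset_eval <- function(fit, x, y, stats, threshold = 0.5) {
  model <- if (inherits(fit, "kan_fit")) fit$model else fit
  xs <- standardize_features(x, stats)
  p <- predict_seizure_prob(model, xs)
  rep <- compute_metrics(p, y, threshold = threshold)
  attr(rep, "stats_provenance") <- "training-split feature_stats"
  rep
}

#' Compact-versus-large generalization experiment
#'
#' Trains two architectures on the same synthetic training set and
#' evaluates both, with frozen weights and training-split
#' standardization, on an out-of-distribution set generated under an
#' [ood_shift()]. Repeated over seeds; the question is directional:
#' does the compact network generalize at least as well as the large one
#' once the data drift?
#'
#' @param specs Two architecture strings, `c(large, small)`.
#' @param seeds Integer vector of replicate seeds (data + training).
#' @param cfg A [sim_config()]; the in-distribution generator.
#' @param shift An [ood_shift()].
#' @param n_train,n_val,n_ood Window counts per replicate.
#' @param epochs,lr,batch_size Training controls.
#' @param pool [pool_features()] argument list; the default band/time
#'   pooling keeps the wide baseline trainable on one CPU.
#' @param spline A [spline_config()].
#' @param verbose Print per-run progress.
#' @return A list of class `generalization_experiment`: `runs` (tibble:
#'   spec, seed, in-sample val AUROC, OOD AUROC, in/out gap) and
#'   `summary` (median OOD AUROC per spec).
#' @export
generalization_experiment <- function(specs = c("I-764-256-O", "I-32-16-O"),
                                      seeds = 1:5,
                                      cfg = sim_config(),
                                      shift = ood_shift(),
                                      n_train = 480L, n_val = 120L,
                                      n_ood = 240L,
                                      epochs = 10L, lr = 1e-3,
                                      batch_size = 64L,
                                      pool = list(),
                                      spline = spline_config(),
                                      verbose = FALSE) {
  runs <- list()
  for (seed in seeds) {
    tr <- make_dataset(cfg, n_windows = n_train, seed = derive_seed(seed, 11L),
                       pool = pool)
    va <- make_dataset(cfg, n_windows = n_val, seed = derive_seed(seed, 12L),
                       pool = pool)
    oo <- make_ood_dataset(cfg, shift, n_windows = n_ood,
                           seed = derive_seed(seed, 13L), pool = pool)
    st <- feature_stats(tr$x)
    xtr <- standardize_features(tr$x, st)
    xva <- standardize_features(va$x, st)
    for (spec in specs) {
      model <- kan_model(spec, input_dim = ncol(xtr), output_dim = 2L,
                         cfg = spline, seed = derive_seed(seed, 21L))
      fit <- train_kan(model, xtr, tr$y, xva, va$y,
                       cfg = train_config(epochs = epochs, lr = lr,
                                          batch_size = batch_size,
                                          seed = derive_seed(seed, 22L),
                                          early_stop = epochs))
      in_auroc <- fit$history$auroc[fit$selected_epoch]
      ood_rep <- cross_dataset_eval(fit, oo$x, oo$y, st)
      if (verbose) {
        cat(sprintf("seed %d  %-12s  val %.3f  ood %.3f\n", seed, spec,
                    in_auroc, ood_rep$auroc))
      }
      runs[[length(runs) + 1L]] <- tibble::tibble(
        spec = spec, seed = seed, val_auroc = in_auroc,
        ood_auroc = ood_rep$auroc, gap = in_auroc - ood_rep$auroc)
    }
  }
  runs <- do.call(rbind, runs)
  med <- vapply(specs, function(s)
    stats::median(runs$ood_auroc[runs$spec == s]), numeric(1))
  summary <- tibble::tibble(spec = specs, median_ood_auroc = med,
                            median_val_auroc = vapply(specs, function(s)
                              stats::median(runs$val_auroc[runs$spec == s]),
                              numeric(1)))
  structure(list(runs = runs, summary = summary),
            class = "generalization_experiment")
}

#' @export
print.generalization_experiment <- function(x, ...) {
  cat("<generalization_experiment>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
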