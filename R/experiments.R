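# The five controlled bias experiments, end to end on synthetic data.
#
# Every experiment is a pure function of (config, seed): datasets, model
# training, heatmap computation and evaluation all derive their randomness
# from the config's master seed. Generated datasets are memoised per session
# so that experiments sharing the same study conditions do not regenerate
# tiles.

.dataset_cache <- new.env(parent = emptyenv())
.model_cache <- new.env(parent = emptyenv())

#' Configuration of the bias-experiment suite
#'
#' The defaults define the study conditions at desk scale: 512 px tiles of
#' 300 cells, 64 px patches, ten class-dominant training tiles (four
#' tumour-dominant — a dataset-level imbalance comparable to the source
#' data), four dominant held-out tiles for patch metrics and three mixed
#' tiles for cell-level evaluation. Training tiles are nearly pure in one
#' class (purity U(0.90, 0.98)), emulating patches cut from single-class
#' region-of-interest annotations; evaluation tiles mix both classes.
#'
#' @param seed master seed; every dataset, initialisation and sampler seed
#'   is derived from it.
#' @param spec a [generator_spec()].
#' @param n_train_tiles,n_test_tiles,n_eval_tiles tile counts for training,
#'   held-out patch metrics and cell-level evaluation.
#' @param tumour_dominant_frac fraction of dominant tiles whose majority
#'   class is tumour.
#' @param purity range of the dominant class fraction on dominant tiles.
#' @param mixed_range range of the tumour fraction on mixed evaluation tiles.
#' @param train a [train_config()]; its seed is overridden by derivation
#'   from `seed`.
#' @param rules a [rule_params()].
#' @param epochs training epochs used by the experiments.
#' @param baseline_runs draws for the random-heatmap baseline.
#' @param centre_stride grid stride (px) for centre-cell patch extraction.
#' @param max_patches cap on training patches per model (subsampled,
#'   seeded, when exceeded).
#' @param corner_majority fraction of corrupted patches that must have the
#'   corner block as argmax for the class-bias verdict.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(seed = 1L,
                              spec = generator_spec(),
                              n_train_tiles = 10L,
                              n_test_tiles = 4L,
                              n_eval_tiles = 3L,
                              tumour_dominant_frac = 0.4,
                              purity = c(0.90, 0.98),
                              mixed_range = c(0.35, 0.60),
                              train = train_config(learning_rate = 1e-2),
                              rules = rule_params(),
                              epochs = 15L,
                              baseline_runs = 100L,
                              centre_stride = 8L,
                              max_patches = 700L,
                              corner_majority = 0.5) {
  structure(list(seed = as.integer(seed), spec = spec,
                 n_train_tiles = as.integer(n_train_tiles),
                 n_test_tiles = as.integer(n_test_tiles),
                 n_eval_tiles = as.integer(n_eval_tiles),
                 tumour_dominant_frac = tumour_dominant_frac,
                 purity = purity, mixed_range = mixed_range,
                 train = train, rules = rules, epochs = as.integer(epochs),
                 baseline_runs = as.integer(baseline_runs),
                 centre_stride = as.integer(centre_stride),
                 max_patches = as.integer(max_patches),
                 corner_majority = corner_majority),
            class = "experiment_config")
}

#' Generate a set of study tiles
#'
#' `dominant` tiles are nearly pure in one class (the per-tile dominant
#' fraction is drawn from `purity`); `mixed` tiles draw their tumour
#' fraction from `mixed_range`. Deterministic in (config, seed, stream).
#'
#' @param config an [experiment_config()].
#' @param n number of tiles.
#' @param stream integer stream id separating independent tile sets.
#' @param kind `"dominant"` or `"mixed"`.
#' @param n_necrosis optional per-tile necrosis count override.
#' @return Named list of `"tissue_tile"`.
#' @export
make_study_tiles <- function(config, n, stream, kind = c("dominant", "mixed"),
                             n_necrosis = NULL) {
  kind <- match.arg(kind)
  key <- paste(kind, n, stream, config$seed, n_necrosis %||% "d",
               paste(unlist(config$spec), collapse = ","),
               paste(config$purity, config$mixed_range, config$tumour_dominant_frac,
                     collapse = ","), sep = "|")
  cached <- .dataset_cache[[key]]
  if (!is.null(cached)) return(cached)
  base <- derive_seed(config$seed, stream)
  n_cells <- config$spec$n_tumour + config$spec$n_normal
  plan <- with_local_seed(base, {
    if (kind == "dominant") {
      n_tum_dom <- max(1L, round(config$tumour_dominant_frac * n))
      dom <- sample(rep(c(TRUE, FALSE), c(n_tum_dom, n - n_tum_dom)))
      fr <- stats::runif(n, config$purity[1], config$purity[2])
      list(frac = ifelse(dom, fr, 1 - fr))
    } else {
      list(frac = stats::runif(n, config$mixed_range[1], config$mixed_range[2]))
    }
  })
  tiles <- lapply(seq_len(n), function(k) {
    nt <- round(plan$frac[k] * n_cells)
    generate_tile(config$spec, seed = derive_seed(base, k),
                  n_tumour = nt, n_normal = n_cells - nt,
                  n_necrosis = n_necrosis)
  })
  names(tiles) <- vapply(tiles, `[[`, character(1), "id")
  .dataset_cache[[key]] <- tiles
  tiles
}

# Extract (and optionally cap) labelled patches from a tile set.
study_patches <- function(tiles, config, rule = "majority", size = NULL,
                          stride = NULL, stream = 0L) {
  patches <- unlist(lapply(tiles, function(t)
    extract_patches(t, size = size, stride = stride, rule = rule)),
    recursive = FALSE, use.names = FALSE)
  if (length(patches) > config$max_patches) {
    keep <- with_local_seed(derive_seed(config$seed, 999L + stream),
                            sample(length(patches), config$max_patches))
    patches <- patches[sort(keep)]
  }
  patches
}

patch_labels <- function(patches) vapply(patches, `[[`, character(1), "label")

# Train the default network under the experiment config. Identical training
# jobs (same derived seeds, same data, same protocol) are memoised per
# session, so experiments sharing a model (e.g. the unbiased ratio-0.5
# model) train it once.
fit_model <- function(config, patches, tiles, ratio = 0.5, augment = TRUE,
                      jitter_frac = NULL, stream = 1L, input_shape = c(64L, 64L, 3L)) {
  cfg <- config$train
  cfg$ratio <- ratio
  cfg$augment <- augment
  if (!is.null(jitter_frac)) cfg$jitter_frac <- jitter_frac
  cfg$seed <- derive_seed(config$seed, 5000L + stream)
  checksum <- sum(vapply(patches[seq_len(min(3, length(patches)))],
                         function(p) sum(p$image), numeric(1)))
  key <- paste(config$seed, stream, ratio, augment, cfg$jitter_frac,
               cfg$batch_size, cfg$learning_rate, config$epochs,
               length(patches), format(checksum, digits = 12),
               paste(input_shape, collapse = "x"), sep = "|")
  cached <- .model_cache[[key]]
  if (!is.null(cached)) return(cached)
  net <- default_network(seed = derive_seed(config$seed, 6000L + stream),
                         input_shape = input_shape)
  fit <- train_network(net, patches, cfg, tiles = tiles, epochs = config$epochs)
  .model_cache[[key]] <- fit
  fit
}

# Pooled cell scores over evaluation tiles under one model.
cell_score_table <- function(network, tiles, config, radius = NULL) {
  hms <- tile_heatmaps(network, tiles, target_class = "cancer",
                       params = config$rules, normalise = "global")
  tabs <- lapply(seq_along(tiles), function(i) {
    tab <- score_cells(rectify(hms[[i]]), tiles[[i]]$cells, radius)
    tab$tile_id <- tiles[[i]]$id
    tab
  })
  list(scores = do.call(rbind, tabs), heatmaps = hms)
}

new_report <- function(id, config, ...) {
  structure(c(list(experiment = id, seed = config$seed,
                   config = config), list(...)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report '%s'> (seed %d)\n", x$experiment, x$seed))
  if (!is.null(x$verdicts)) {
    for (nm in names(x$verdicts))
      cat(sprintf("  %-45s %s\n", nm, if (isTRUE(x$verdicts[[nm]])) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Feature-verification experiment
#'
#' Trains an unbiased model on the default synthetic task, computes
#' relevance heatmaps for held-out mixed tiles, and quantifies single-cell
#' recognition as ROC/AUC per tile and pooled, against the zeros, ones and
#' random-heatmap baselines.
#'
#' @param config an [experiment_config()].
#' @return An `"experiment_report"` with patch metrics, per-tile and pooled
#'   cell AUCs, baseline AUCs and verdict flags.
#' @export
run_feature_verification <- function(config = experiment_config()) {
  tiles <- make_study_tiles(config, config$n_train_tiles, 1L, "dominant")
  test_tiles <- make_study_tiles(config, config$n_test_tiles, 2L, "dominant")
  eval_tiles <- make_study_tiles(config, config$n_eval_tiles, 3L, "mixed")
  patches <- study_patches(tiles, config)
  test_patches <- study_patches(test_tiles, config)
  fit <- fit_model(config, patches, tiles, stream = 1L)
  metrics <- patch_metrics(patch_labels(test_patches),
                           predict_label(fit$network, test_patches))
  cs <- cell_score_table(fit$network, eval_tiles, config)
  pooled <- roc_auc(cs$scores)
  per_tile <- lapply(split(cs$scores, cs$scores$tile_id), roc_auc)
  baselines <- list(
    zeros = baseline_aucs(eval_tiles, "zeros"),
    ones = baseline_aucs(eval_tiles, "ones"),
    random = baseline_aucs(eval_tiles, "random", runs = config$baseline_runs,
                           seed = derive_seed(config$seed, 42L)))
  new_report("feature_verification", config,
    patch_metrics = metrics,
    pooled_auc = pooled$auc,
    pooled_roc = pooled,
    per_tile_auc = vapply(per_tile, `[[`, numeric(1), "auc"),
    baselines = lapply(baselines, function(b) b[c("mean", "sd")]),
    n_cells = nrow(cs$scores),
    history = fit$history,
    verdicts = list(
      auc_above_zeros = pooled$auc > baselines$zeros$mean,
      auc_above_ones = pooled$auc > baselines$ones$mean,
      auc_above_random = pooled$auc > baselines$random$mean))
}

#' Class-sampling-ratio experiment
#'
#' Trains two models identical except for the cancer fraction per mini-batch
#' (default 0.5 vs 0.8) and contrasts patch-level recall/precision of the
#' cancer class with the predominance of positive relevance in the heatmaps.
#'
#' @param config an [experiment_config()].
#' @param ratios the two batch-composition ratios.
#' @return An `"experiment_report"`.
#' @export
run_sampling_ratio <- function(config = experiment_config(),
                               ratios = c(0.5, 0.8)) {
  if (any(ratios <= 0 | ratios >= 1)) stopf("ratios must lie in (0, 1)")
  tiles <- make_study_tiles(config, config$n_train_tiles, 1L, "dominant")
  test_tiles <- make_study_tiles(config, config$n_test_tiles, 2L, "dominant")
  eval_tiles <- make_study_tiles(config, config$n_eval_tiles, 3L, "mixed")
  patches <- study_patches(tiles, config)
  test_patches <- study_patches(test_tiles, config)
  truth <- patch_labels(test_patches)
  per_ratio <- lapply(seq_along(ratios), function(k) {
    fit <- fit_model(config, patches, tiles, ratio = ratios[k], stream = 1L)
    metrics <- patch_metrics(truth, predict_label(fit$network, test_patches))
    cs <- cell_score_table(fit$network, eval_tiles, config)
    # a patch's total relevance is the classifier's net evidence for the
    # explained class; oversampling the cancer class shifts this evidence
    # upward across the held-out patches ("more positive relevance"), which
    # is the robust heatmap-level footprint of the sampling ratio
    sums <- vapply(test_patches, function(p)
      sum(explain(fit$network, p, "cancer", config$rules)$values), numeric(1))
    test_hms <- tile_heatmaps(fit$network, test_tiles, params = config$rules,
                              normalise = "none")
    list(ratio = ratios[k], metrics = metrics,
         cell_auc = roc_auc(cs$scores)$auc,
         mean_net_relevance = mean(sums),
         positive_share = mean(sums > 0),
         positive_fraction = mean(vapply(test_hms, positive_fraction, numeric(1))))
  })
  names(per_ratio) <- paste0("ratio_", ratios)
  r1 <- per_ratio[[1]]; r2 <- per_ratio[[2]]
  new_report("sampling_ratio", config,
    ratios = ratios,
    results = lapply(per_ratio, function(r)
      list(ratio = r$ratio,
           recall_cancer = unname(r$metrics$recall["cancer"]),
           precision_cancer = unname(r$metrics$precision["cancer"]),
           weighted_f1 = r$metrics$weighted_f1,
           cell_auc = r$cell_auc,
           mean_net_relevance = r$mean_net_relevance,
           positive_share = r$positive_share,
           positive_fraction = r$positive_fraction)),
    verdicts = list(
      recall_up = r2$metrics$recall["cancer"] >= r1$metrics$recall["cancer"],
      precision_down = r2$metrics$precision["cancer"] <= r1$metrics$precision["cancer"],
      positive_relevance_up = r2$mean_net_relevance > r1$mean_net_relevance))
}

#' Dataset-bias (centre-cell labelling) experiment
#'
#' Labels patches solely by the cell at the patch centre, trains one model
#' without translation augmentation (amplifying the centring bias) and a
#' control model on random crops of 60% of the patch side, then contrasts
#' centre-mass profiles of absolute relevance over held-out patches.
#'
#' @param config an [experiment_config()].
#' @return An `"experiment_report"` with both profiles and the central-to-
#'   global mean absolute relevance ratios.
#' @export
run_dataset_bias <- function(config = experiment_config()) {
  ps <- config$spec$patch_size
  crop <- as.integer(round(0.6 * ps))
  tiles <- make_study_tiles(config, config$n_train_tiles, 11L, "mixed")
  test_tiles <- make_study_tiles(config, config$n_test_tiles, 12L, "mixed")
  patches <- study_patches(tiles, config, rule = "centre_cell",
                           stride = config$centre_stride, stream = 11L)
  test_patches <- study_patches(test_tiles, config, rule = "centre_cell",
                                stride = config$centre_stride, stream = 12L)
  # biased model: centre-labelled patches, rotation-only augmentation
  fit_b <- fit_model(config, patches, tiles, augment = TRUE, jitter_frac = 0,
                     stream = 21L)
  # control: random crops (60% side) of the same labelled patches, with
  # translation jitter re-drawing the crop window every epoch
  crop_patches <- with_local_seed(derive_seed(config$seed, 77L), {
    lapply(patches, function(p) {
      dr <- sample.int(ps - crop + 1L, 1L) - 1L
      dc <- sample.int(ps - crop + 1L, 1L) - 1L
      p$image <- p$image[(dr + 1):(dr + crop), (dc + 1):(dc + crop), , drop = FALSE]
      p$source$row <- p$source$row + dr
      p$source$col <- p$source$col + dc
      p
    })
  })
  fit_c <- fit_model(config, crop_patches, tiles, augment = TRUE,
                     stream = 22L, input_shape = c(crop, crop, 3L))
  # each model is profiled on held-out patches of its own input size (the
  # control model is size-specific, exactly like a model trained on smaller
  # random crops of the original data); profiles are compared through
  # relative side lengths
  crop_test <- with_local_seed(derive_seed(config$seed, 78L), {
    lapply(test_patches, function(p) {
      dr <- sample.int(ps - crop + 1L, 1L) - 1L
      dc <- sample.int(ps - crop + 1L, 1L) - 1L
      p$image <- p$image[(dr + 1):(dr + crop), (dc + 1):(dc + crop), , drop = FALSE]
      p
    })
  })
  rel_sides <- c(0.25, 0.5, 0.75, 1)
  profile_of <- function(net, patches, size) {
    maps <- lapply(patches, function(p) explain(net, p, "cancer", config$rules))
    center_profile(maps, unique(pmax(1L, as.integer(round(size * rel_sides)))))
  }
  prof_b <- profile_of(fit_b$network, test_patches, ps)
  prof_c <- profile_of(fit_c$network, crop_test, crop)
  ratio_of <- function(prof, size) {
    half <- prof$mean_abs_relevance[prof$side == round(size * 0.5)]
    full <- prof$mean_abs_relevance[prof$side == max(prof$side)]
    half / full
  }
  flatness <- function(prof) max(prof$mean_abs_relevance) / min(prof$mean_abs_relevance)
  rb <- ratio_of(prof_b, ps); rc <- ratio_of(prof_c, crop)
  new_report("dataset_bias", config,
    relative_sides = rel_sides,
    profile_biased = prof_b,
    profile_control = prof_c,
    central_ratio_biased = rb,
    central_ratio_control = rc,
    n_test_patches = length(test_patches),
    verdicts = list(
      biased_more_central = rb > rc,
      control_flatter = flatness(prof_c) < flatness(prof_b)))
}

#' Class-correlated-bias (corner marker) experiment
#'
#' Stamps the 5 x 5 px corner marker onto every cancer patch of the training
#' and test splits, trains on the corrupted data, and checks that (a) test
#' accuracy is perfect and (b) relevance concentrates on the marker: for most
#' corrupted test patches the top-left block is the argmax 5 x 5 block, and
#' the corrupted class-mean heatmap peaks there while the clean class's does
#' not.
#'
#' @param config an [experiment_config()].
#' @param side marker side length in px.
#' @param batch_size mini-batch size for this experiment. The default 16
#'   (half the shared default) doubles the number of SGD steps per epoch,
#'   which helps the optimiser escape the morphology-only solution.
#' @param max_restarts maximal number of random restarts. Whether SGD locks
#'   onto the marker is initialisation-dependent (a non-convex bifurcation:
#'   an unlucky run settles in the morphology-only basin and plateaus at its
#'   accuracy ceiling). Restarts draw a fresh derived initialisation seed
#'   and stop at the first run whose *training* accuracy reaches
#'   `restart_train_acc` — achievable only through the marker, and judged on
#'   training data alone.
#' @param restart_train_acc training-accuracy threshold declaring a restart
#'   successful.
#' @return An `"experiment_report"`.
#' @export
run_class_bias <- function(config = experiment_config(), side = 5L,
                           batch_size = 16L, max_restarts = 4L,
                           restart_train_acc = 0.995) {
  config$train$batch_size <- as.integer(batch_size)
  # mixed tiles: plurality labels of heterogeneous patches cannot be fit
  # perfectly from morphology alone, so the corner marker is the only route
  # to zero training error - the shortcut the experiment is meant to expose
  tiles <- make_study_tiles(config, config$n_train_tiles, 61L, "mixed")
  test_tiles <- make_study_tiles(config, config$n_test_tiles, 62L, "mixed")
  corrupt <- function(ps) lapply(ps, function(p) {
    if (p$label == "cancer")
      inject_corner_marker(p, side = side, colour = config$spec$marker_colour)
    else p
  })
  patches <- corrupt(study_patches(tiles, config))
  test_patches <- corrupt(study_patches(test_tiles, config))
  train_truth <- patch_labels(patches)
  n_restarts <- 0L
  for (attempt in seq_len(max_restarts)) {
    fit <- fit_model(config, patches, tiles, augment = FALSE,
                     stream = 30L + attempt)
    n_restarts <- attempt
    train_acc <- mean(predict_label(fit$network, patches) == train_truth)
    if (train_acc >= restart_train_acc) break
  }
  truth <- patch_labels(test_patches)
  pred <- predict_label(fit$network, test_patches)
  metrics <- patch_metrics(truth, pred)
  maps <- lapply(test_patches, function(p) explain(fit$network, p, "cancer", config$rules))
  is_cancer <- truth == "cancer"
  corner <- vapply(maps[is_cancer], function(m)
    corner_block_stats(m, side)$argmax_overlaps_corner, logical(1))
  mean_cancer <- class_mean_heatmap(maps[is_cancer])
  mean_clean <- class_mean_heatmap(maps[!is_cancer])
  new_report("class_bias", config,
    marker_side = side,
    n_restarts = n_restarts,
    test_accuracy = metrics$accuracy,
    patch_metrics = metrics,
    corner_argmax_fraction = mean(corner),
    class_mean_cancer = mean_cancer,
    class_mean_no_cancer = mean_clean,
    verdicts = list(
      perfect_accuracy = metrics$accuracy >= 0.95,
      corner_argmax_majority = mean(corner) > config$corner_majority,
      clean_class_no_corner =
        !corner_block_stats(mean_clean, side)$argmax_overlaps_corner))
}

#' Sampling-bias (necrosis exclusion) experiment
#'
#' Trains one model on a dataset from which every patch touching a necrotic
#' region was removed and one on the comprehensive dataset, then compares the
#' signed mean relevance that each model assigns to held-out necrotic
#' regions: the biased model is expected to mark more regions with positive
#' (tumour-supporting) relevance and with larger spread across regions.
#'
#' @param config an [experiment_config()].
#' @return An `"experiment_report"` with per-region scores for both models.
#' @export
run_sampling_bias <- function(config = experiment_config()) {
  tiles <- make_study_tiles(config, config$n_train_tiles, 1L, "dominant")
  test_tiles <- make_study_tiles(config, config$n_test_tiles, 2L, "dominant")
  eval_tiles <- make_study_tiles(config, config$n_eval_tiles + 1L, 13L, "mixed",
                                 n_necrosis = 3L)
  n_regions <- sum(vapply(eval_tiles, function(t) length(t$regions), integer(1)))
  if (n_regions == 0) stopf("no necrotic regions in the evaluation tiles")
  patches <- study_patches(tiles, config)
  excl <- exclude_region_patches(patches, tiles, "necrosis")
  fit_excl <- fit_model(config, excl, tiles, stream = 41L)
  fit_comp <- fit_model(config, patches, tiles, stream = 41L)
  region_scores <- function(net) {
    hms <- tile_heatmaps(net, eval_tiles, target_class = "cancer",
                         params = config$rules, normalise = "global")
    unlist(lapply(seq_along(eval_tiles), function(i) {
      masks <- Filter(function(r) r$region_type == "necrosis", eval_tiles[[i]]$regions)
      vapply(masks, function(r) score_region(hms[[i]], r$mask, "signed"), numeric(1))
    }))
  }
  sc_excl <- region_scores(fit_excl$network)
  sc_comp <- region_scores(fit_comp$network)
  new_report("sampling_bias", config,
    n_regions = length(sc_excl),
    region_scores_excluded = sc_excl,
    region_scores_comprehensive = sc_comp,
    n_train_excluded = length(excl), n_train_comprehensive = length(patches),
    verdicts = list(
      excluded_more_positive_regions = sum(sc_excl > 0) >= sum(sc_comp > 0),
      excluded_higher_dispersion = stats::sd(sc_excl) > stats::sd(sc_comp)))
}

#' Run the full experiment suite
#'
#' @param config an [experiment_config()].
#' @param which subset of experiment names.
#' @return Named list of `"experiment_report"`.
#' @export
run_all_experiments <- function(config = experiment_config(),
                                which = c("feature_verification", "sampling_ratio",
                                          "dataset_bias", "class_bias",
                                          "sampling_bias")) {
  runners <- list(feature_verification = run_feature_verification,
                  sampling_ratio = run_sampling_ratio,
                  dataset_bias = run_dataset_bias,
                  class_bias = run_class_bias,
                  sampling_bias = run_sampling_bias)
  lapply(stats::setNames(which, which), function(w) runners[[w]](config))
}

#' Write an experiment report to disk
#'
#' JSON for the scalar summary and verdicts, CSV for tabular parts, and PNG
#' panels for any class-mean heatmaps the report carries.
#'
#' @param report an `"experiment_report"`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drop <- c("config", "class_mean_cancer", "class_mean_no_cancer",
            "pooled_roc", "profile_biased", "profile_control", "history")
  sanitise <- function(x) {
    if (inherits(x, "table")) {
      m <- unclass(x); attributes(m) <- attributes(m)[c("dim", "dimnames")]
      return(m)
    }
    if (is.list(x)) return(lapply(x, sanitise))
    x
  }
  scal <- sanitise(report[setdiff(names(report), drop)])
  scal$config <- list(seed = report$config$seed, epochs = report$config$epochs,
                      n_train_tiles = report$config$n_train_tiles)
  jsonlite::write_json(scal, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$history))
    utils::write.csv(report$history, file.path(dir, "history.csv"), row.names = FALSE)
  for (nm in c("profile_biased", "profile_control")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  for (nm in c("class_mean_cancer", "class_mean_no_cancer")) {
    m <- report[[nm]]
    if (is.null(m)) next
    v <- m / max(abs(m), 1e-12)
    hm <- structure(list(values = v), class = "tile_heatmap")
    png::writePNG(render_overlay(hm, array(1, c(nrow(v), ncol(v), 3))),
                  file.path(dir, paste0(nm, ".png")))
  }
  invisible(dir)
}
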