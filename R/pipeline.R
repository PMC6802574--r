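#' Pipeline configuration
#'
#' One declarative object holding every choice the identification pipeline
#' makes, with every stochastic component's seed explicit, so runs are
#' reproducible and ablation grids are just lists of configs. Unknown keys
#' are rejected by name.
#'
#' @param manifest Path to a manifest CSV, or a \code{manifest} object.
#' @param image_size Square input side S (>= 32, divisible by 32).
#' @param resize_mode \code{"preserve_aspect"} or \code{"distort"}.
#' @param pad_seed Seed for random-pixel padding.
#' @param backbone \code{"fixture"} or \code{"vgg16"}.
#' @param backbone_seed Seed for the fixture backbone's weights.
#' @param weights_path RDS weight container for the pretrained backbone.
#' @param blocks Blocks whose features are used (fusion set, ascending
#'   order), subset of c1..c5.
#' @param level Pooling level N (1 = global pooling; otherwise an admissible
#'   divisor of the padded reference side, e.g. 2, 4, 7, 14 or 28 at S=416).
#' @param pooling \code{"average"} or \code{"max"}.
#' @param signed_sqrt Apply signed-square-root normalisation (default TRUE).
#' @param l2 Apply l2 normalisation (default FALSE).
#' @param cost,tolerance Classifier settings, see [classifier_config()].
#' @param folds Cross-validation fold count.
#' @param grouping \code{"none"} (stratified by image) or
#'   \code{"by_specimen"}.
#' @param fold_seed Seed for fold assignment.
#' @param classifier_seed Seed recorded with classifier training.
#' @param cache_dir Optional directory for the per-image block-feature cache;
#'   \code{NULL} disables caching.
#' @param top Suggestion depth for top-k reporting.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(manifest = NULL,
                            image_size = 224L,
                            resize_mode = "preserve_aspect",
                            pad_seed = 1L,
                            backbone = "fixture",
                            backbone_seed = 42L,
                            weights_path = NULL,
                            blocks = "c5",
                            level = 1L,
                            pooling = "average",
                            signed_sqrt = TRUE,
                            l2 = FALSE,
                            cost = 1,
                            tolerance = 1e-4,
                            folds = 10L,
                            grouping = "none",
                            fold_seed = 1L,
                            classifier_seed = 1L,
                            cache_dir = NULL,
                            top = 3L) {
  config <- list(manifest = manifest, image_size = as.integer(image_size),
                 resize_mode = resize_mode, pad_seed = pad_seed,
                 backbone = backbone, backbone_seed = backbone_seed,
                 weights_path = weights_path, blocks = blocks,
                 level = as.integer(level), pooling = pooling,
                 signed_sqrt = signed_sqrt, l2 = l2, cost = cost,
                 tolerance = tolerance, folds = as.integer(folds),
                 grouping = grouping, fold_seed = fold_seed,
                 classifier_seed = classifier_seed, cache_dir = cache_dir,
                 top = as.integer(top))
  validate_pipeline_config(config)
}

#' Validate a pipeline configuration list
#'
#' @param config A named list of configuration values.
#' @return The validated \code{pipeline_config}.
#' @export
validate_pipeline_config <- function(config) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("config error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  defaults <- formals(pipeline_config)
  for (key in setdiff(known, names(config))) {
    config[[key]] <- eval(defaults[[key]])
  }
  resize_spec(config$image_size, config$resize_mode, config$pad_seed)  # checks
  stopifnot(config$backbone %in% c("fixture", "vgg16"),
            all(config$blocks %in% paste0("c", 1:5)),
            config$pooling %in% c("average", "max"),
            config$grouping %in% c("none", "by_specimen"),
            config$level >= 1L, config$folds >= 2L)
  structure(config, class = "pipeline_config")
}

config_digest <- function(config) {
  fields <- config[setdiff(names(config), "manifest")]
  object_digest(fields)
}

resolve_manifest <- function(config) {
  m <- config$manifest
  if (is.null(m)) stop("config error: no manifest given")
  if (inherits(m, "manifest")) m else read_manifest(m)
}

resolve_backbone <- function(config) {
  if (config$backbone == "fixture") {
    make_fixture_backbone(config$backbone_seed)
  } else {
    vgg16_backbone(config$weights_path)
  }
}

# Tap points implied by the feature path: the global path (level 1) taps
# every block after its pooling layer; the intermediate path taps c5 before
# its final pooling so c3/c4/c5 share the reference side.
default_tap_points <- function(blocks, level) {
  stats::setNames(ifelse(blocks == "c5" & level > 1L, "pre_pool", "post_pool"),
                  blocks)
}

#' Compute the feature matrix for every record of a manifest
#'
#' Loads, resizes and forward-passes each image, then builds the configured
#' feature vector. When \code{config$cache_dir} is set, per-image block
#' feature matrices are cached on disk keyed by image path, geometry, resize
#' settings, backbone identity, block and tap point, so that pooling/fusion/
#' classifier experiments re-run without repeating forward passes.
#'
#' @param manifest A \code{manifest}.
#' @param config A \code{pipeline_config}.
#' @return Numeric n x d matrix, rows aligned with the manifest records.
#' @export
compute_features <- function(manifest, config) {
  config <- validate_pipeline_config(config)
  backbone <- resolve_backbone(config)
  spec <- resize_spec(config$image_size, config$resize_mode, config$pad_seed)
  taps <- default_tap_points(config$blocks, config$level)
  rows <- lapply(manifest$path, function(p) {
    fms <- cached_block_features(p, backbone, spec, config, taps)
    feature_vector(fms, level = config$level, mode = config$pooling,
                   use_signed_sqrt = config$signed_sqrt, use_l2 = config$l2)
  })
  do.call(rbind, rows)
}

cached_block_features <- function(path, backbone, spec, config, taps) {
  use_cache <- !is.null(config$cache_dir)
  if (use_cache) {
    dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  key_base <- list(path = normalizePath(path), s = spec$target_side,
                   mode = spec$mode, pad_seed = spec$pad_seed,
                   backbone = config$backbone, seed = config$backbone_seed)
  cache_file <- function(block) {
    file.path(config$cache_dir,
              paste0(object_digest(c(key_base, block = block,
                                     tap = taps[[block]])), ".rds"))
  }
  fms <- list()
  missing_blocks <- config$blocks
  if (use_cache) {
    for (blk in config$blocks) {
      f <- cache_file(blk)
      if (file.exists(f)) {
        fms[[blk]] <- readRDS(f)
        missing_blocks <- setdiff(missing_blocks, blk)
      }
    }
  }
  if (length(missing_blocks) > 0) {
    img <- resize_image(load_image(path), spec)
    fresh <- extract_features(backbone, img, missing_blocks,
                              taps[missing_blocks])
    for (blk in missing_blocks) {
      fms[[blk]] <- fresh[[blk]]
      if (use_cache) saveRDS(fresh[[blk]], cache_file(blk))
    }
  }
  fms[config$blocks]
}

#' Run the full identification pipeline under one configuration
#'
#' Reads the manifest, computes feature vectors, builds the fold plan
#' (stratified or specimen-grouped) and returns the cross-validated
#' evaluation report, annotated with the configuration and its digest.
#'
#' @param config A \code{pipeline_config}.
#' @return An \code{evaluation_report} with \code{config} and
#'   \code{config_digest} fields attached.
#' @export
evaluate_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  manifest <- resolve_manifest(config)
  x <- compute_features(manifest, config)
  plan <- if (config$grouping == "by_specimen") {
    grouped_folds(manifest, config$folds, config$fold_seed)
  } else {
    stratified_folds(manifest, config$folds, config$fold_seed)
  }
  report <- cross_validate(x, manifest$label, plan,
                           classifier_config(config$cost, config$tolerance,
                                             config$classifier_seed),
                           top = config$top)
  report$config <- config
  report$config_digest <- config_digest(config)
  report
}

#' Run an ablation grid
#'
#' Evaluates the pipeline over the Cartesian product of the supplied config
#' overrides (e.g. \code{list(pooling = c("average", "max"), blocks =
#' list("c4", "c5"))}) and returns one tidy row per combination with its
#' accuracy and error rate. Sharing a \code{cache_dir} in the base config
#' makes the grid reuse forward passes across combinations.
#'
#' @param base_config A \code{pipeline_config} used for all fixed settings.
#' @param grid Named list: each element a vector (or list, for non-scalar
#'   values such as fusion sets) of values to sweep.
#' @return Data frame with one column per swept key (list-valued sweeps are
#'   collapsed to \code{+}-joined strings) plus \code{accuracy} and
#'   \code{error_rate}.
#' @export
grid_evaluate <- function(base_config, grid) {
  stopifnot(length(grid) >= 1, !is.null(names(grid)))
  combos <- expand.grid(lapply(grid, seq_along))
  out <- lapply(seq_len(nrow(combos)), function(i) {
    config <- base_config
    shown <- list()
    for (key in names(grid)) {
      value <- grid[[key]][[combos[i, key]]]
      config[[key]] <- value
      shown[[key]] <- paste(value, collapse = "+")
    }
    report <- evaluate_pipeline(validate_pipeline_config(config))
    cbind(as.data.frame(shown, stringsAsFactors = FALSE),
          accuracy = report$accuracy, error_rate = report$error_rate)
  })
  do.call(rbind, out)
}

#' Write an evaluation report to disk
#'
#' Emits \code{summary.json} (overall metrics, top-k tables, configuration,
#' seeds, config digest and package version), \code{per_category.csv} and
#' \code{confusion.csv} under \code{dir}.
#'
#' @param report An \code{evaluation_report} from [evaluate_pipeline()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- report$config
  summary <- list(
    accuracy = report$accuracy,
    error_rate = report$error_rate,
    n = report$n,
    per_fold = unname(report$per_fold),
    top_k_cumulative = as.list(report$top_k_cumulative),
    top_k_per_rank = as.list(report$top_k_per_rank),
    config = if (!is.null(config)) {
      c(config[setdiff(names(config), "manifest")],
        list(manifest = if (is.character(config$manifest)) config$manifest
             else "<in-memory manifest>"))
    },
    config_digest = report$config_digest,
    package_version = as.character(utils::packageVersion("deepident"))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report$per_category, file.path(dir, "per_category.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  invisible(dir)
}
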