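# End-to-end orchestration: synthetic dataset generation, feature
# extraction from image pairs, and the full training/evaluation experiment
# (rare filter -> repeated splits -> standardization -> five algorithms ->
# hierarchical, single-level, local-pool and novel-species evaluation).
# Every output carries the run seed and a config hash for reproducibility.

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

.write_with_meta <- function(df, path, seed, hash) {
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(seed = seed, config_hash = hash,
               package = "pitfallID",
               version = as.character(utils::packageVersion("pitfallID")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Run the full classification experiment
#'
#' Executes the pipeline on a feature table: separates rare species,
#' makes repeated 70:30 splits, standardizes on training rows, trains
#' every requested algorithm, and evaluates with the hierarchical
#' classifier at all ranks, single-level classifiers per rank, local
#' species-pool reranking, and the novel-species protocol on the rare
#' partition.
#'
#' @param table feature table (68 features + `species` + `site` +
#'   `specimen_id`).
#' @param tax a `taxonomy_table`.
#' @param pools site-pool data.frame (`site_id`, `species`).
#' @param algorithms character vector of algorithms to run (baseline is
#'   always added).
#' @param min_obs rare-species threshold (see [filter_rare()]).
#' @param ratio,n_repeats split parameters (see [make_splits()]).
#' @param ranks evaluation ranks (default: all taxonomy ranks).
#' @param seed global seed; all per-repeat and per-algorithm seeds derive
#'   from it.
#' @param tuning_mode,grids tuning controls: `tuning_mode` as in
#'   [model_spec()]; `grids` an optional named list of per-algorithm grids.
#' @param single_level run the single-level classifiers too.
#' @param fit_on standardization fit mode (see [standardize()]).
#' @param confusion_algorithm algorithm whose species-level confusion
#'   matrix is averaged over repeats.
#' @param ntree,cv_folds,ann_maxit passed to [model_spec()].
#' @param verbose print per-stage progress.
#' @return An `evaluation_report`: list with `metrics` (tidy data.frame:
#'   algorithm, mode, rank, metric, repeat_index, value), `summary`
#'   (means over repeats), `local`, `novel`, `confusion`, `seed`,
#'   `n_repeats`, and bookkeeping.
#' @export
run_experiment <- function(table, tax, pools,
                           algorithms = c("knn", "lda", "nb", "rf", "ann"),
                           min_obs = 31, ratio = 0.7, n_repeats = 10,
                           ranks = tax$ranks, seed = 1,
                           tuning_mode = "inner-cv", grids = list(),
                           single_level = TRUE, fit_on = "train",
                           confusion_algorithm = "lda",
                           ntree = 500, cv_folds = 5, ann_maxit = 300,
                           verbose = FALSE) {
  validate_feature_table(table, tax)
  say <- function(...) if (verbose) message(sprintf(...))
  algorithms <- unique(c(algorithms, "baseline"))
  parts <- filter_rare(table, min_obs = min_obs)
  say("filter_rare: %d common rows (%d species), %d rare rows (%d species)",
      nrow(parts$common), length(unique(parts$common$species)),
      nrow(parts$rare), length(unique(parts$rare$species)))
  splits <- suppressWarnings(
    make_splits(parts$common, ratio = ratio, n_repeats = n_repeats,
                seed = seed))

  feats <- feature_manifest()
  metrics <- list(); local_rows <- list(); novel_rows <- list()
  conf_pred <- list(); conf_truth <- list()

  for (s in splits) {
    std <- standardize(parts$common, s, fit_on = fit_on)
    sites_test <- parts$common$site[s$test]
    rare_x <- NULL
    if (nrow(parts$rare) > 0) {
      rare_raw <- as.matrix(parts$rare[, feats])
      rare_x <- sweep(sweep(rare_raw, 2, std$center), 2, std$scale, "/")
    }
    for (alg in algorithms) {
      spec <- model_spec(alg, grid = grids[[alg]],
                         tuning_mode = tuning_mode,
                         seed = seed + 101L * s$repeat_index,
                         ntree = ntree, cv_folds = cv_folds,
                         ann_maxit = ann_maxit)
      model <- train_model(spec, std$train, std$train_labels,
                           validation = list(x = std$test,
                                             y = std$test_labels))
      preds <- predict_proba(model, std$test)
      h <- hierarchical_evaluate(preds, std$test_labels, tax, ranks)
      h$algorithm <- alg; h$mode <- "hierarchical"
      h$repeat_index <- s$repeat_index
      metrics[[length(metrics) + 1]] <- h

      if (!is.null(pools)) {
        lf <- local_filter(preds, sites_test, pools,
                           truth = std$test_labels)
        local_rows[[length(local_rows) + 1]] <- data.frame(
          algorithm = alg, repeat_index = s$repeat_index,
          local_accuracy = lf$local_accuracy,
          unrestricted_accuracy = lf$unrestricted_accuracy,
          n_sites_used = sum(!lf$per_site$singleton),
          stringsAsFactors = FALSE)
      }
      if (!is.null(rare_x) && alg != "baseline") {
        nv <- novel_species_evaluate(model, rare_x, parts$rare$species, tax)
        nv$algorithm <- alg; nv$repeat_index <- s$repeat_index
        novel_rows[[length(novel_rows) + 1]] <- nv
      }
      if (alg == confusion_algorithm) {
        conf_pred[[length(conf_pred) + 1]] <- top1_labels(preds)
        conf_truth[[length(conf_truth) + 1]] <- std$test_labels
      }
    }
    say("repeat %d/%d done", s$repeat_index, n_repeats)
  }

  # single-level classifiers: ranks above species retrain with lifted
  # labels; at the species rank the single-level and hierarchical
  # classifiers coincide by construction, so species rows are copied
  if (single_level) {
    upper <- setdiff(ranks, tax$ranks[1])
    for (alg in algorithms) {
      spec <- model_spec(alg, grid = grids[[alg]],
                         tuning_mode = tuning_mode, seed = seed + 17L,
                         ntree = ntree, cv_folds = cv_folds,
                         ann_maxit = ann_maxit)
      sl <- single_level_evaluate(spec, parts$common, splits, tax,
                                  ranks = upper, fit_on = fit_on)
      sl$algorithm <- alg; sl$mode <- "single_level"
      sl$single_class <- NULL
      metrics[[length(metrics) + 1]] <- sl
      say("single-level %s done", alg)
    }
    hier <- do.call(rbind, metrics)
    sp <- hier[hier$mode == "hierarchical" & hier$rank == tax$ranks[1], ]
    if (nrow(sp) > 0) {
      sp$mode <- "single_level"
      metrics[[length(metrics) + 1]] <- sp
    }
  }

  metrics <- do.call(rbind, metrics)[
    , c("algorithm", "mode", "rank", "metric", "repeat_index", "value")]
  rownames(metrics) <- NULL
  summary_df <- stats::aggregate(value ~ algorithm + mode + rank + metric,
                                 data = metrics, FUN = mean)
  local_df <- if (length(local_rows)) do.call(rbind, local_rows) else NULL
  novel_df <- if (length(novel_rows)) do.call(rbind, novel_rows) else NULL
  confusion <- if (length(conf_pred))
    confusion_matrix_avg(conf_pred, conf_truth) else NULL

  structure(list(metrics = metrics, summary = summary_df,
                 local = local_df, novel = novel_df,
                 confusion = confusion,
                 seed = seed, n_repeats = n_repeats,
                 algorithms = algorithms, ranks = ranks,
                 rare_species = unique(parts$rare$species)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d algorithms x %d ranks x %d repeats\n",
              length(x$algorithms), length(x$ranks), x$n_repeats))
  sp <- x$summary[x$summary$rank == x$ranks[1] &
                    x$summary$metric == "top1" &
                    x$summary$mode == "hierarchical", ]
  if (nrow(sp) > 0) {
    cat("species-level top-1 (mean over repeats):\n")
    for (i in order(-sp$value))
      cat(sprintf("  %-9s %.3f\n", sp$algorithm[i], sp$value[i]))
  }
  if (!is.null(x$local)) {
    agg <- stats::aggregate(local_accuracy ~ algorithm, data = x$local,
                            FUN = mean)
    best <- agg[which.max(agg$local_accuracy), ]
    cat(sprintf("best local-pool accuracy: %s %.3f\n",
                best$algorithm, best$local_accuracy))
  }
  invisible(x)
}

#' Generate and write a synthetic dataset bundle
#'
#' Writes taxonomy, feature and site-pool CSVs (and their seed/hash
#' sidecars) that the experiment stage reads back.
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
run_synth <- function(config = synthetic_preset("reduced"),
                      out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- make_synthetic_dataset(config)
  hash <- .config_hash(unclass(config))
  paths <- list(
    taxonomy = file.path(out_dir, "taxonomy.csv"),
    features = file.path(out_dir, "features.csv"),
    pools = file.path(out_dir, "pools.csv"))
  .write_with_meta(ds$taxonomy$table, paths$taxonomy, config$seed, hash)
  .write_with_meta(ds$table, paths$features, config$seed, hash)
  .write_with_meta(ds$pools, paths$pools, config$seed, hash)
  invisible(paths)
}

#' Extract features from a directory of image pairs
#'
#' Discovers dorsal/ventral pairs by naming convention
#' (`<event>_dorsal.png` / `<event>_ventral.png`), runs the imaging
#' pipeline on each event, and writes one feature CSV plus labeled ROI
#' audit maps.
#'
#' @param image_dir directory of 8-bit RGB PNGs.
#' @param out_dir output directory.
#' @param resolution pixels per mm of the images.
#' @param min_area_px debris filter passed to [find_regions()].
#' @param seed recorded in output metadata (extraction is deterministic).
#' @return Invisibly, the feature CSV path.
#' @export
run_extract <- function(image_dir, out_dir = ".", resolution = 12,
                        min_area_px = 50, seed = 1) {
  files <- list.files(image_dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no PNG images found in ", image_dir)
  dorsal <- grep("_dorsal\\.png$", files, value = TRUE)
  events <- sub("_dorsal\\.png$", "", basename(dorsal))
  unpaired <- files[!grepl("_(dorsal|ventral)\\.png$", files)]
  if (length(unpaired) > 0)
    stop("image(s) not following the <event>_dorsal/_ventral convention: ",
         paste(basename(unpaired), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ev in events) {
    vfile <- file.path(image_dir, paste0(ev, "_ventral.png"))
    if (!file.exists(vfile))
      stop("unpaired image: missing ventral view for event ", ev)
    di <- read_batch_image(file.path(image_dir, paste0(ev, "_dorsal.png")),
                           resolution, "dorsal")
    vi <- read_batch_image(vfile, resolution, "ventral")
    md <- binarize(di); mv <- binarize(vi)
    rd <- find_regions(md, min_area_px); rv <- find_regions(mv, min_area_px)
    write_region_map(rd, dim(md), file.path(out_dir, paste0(ev, "_dorsal_roi.png")))
    write_region_map(rv, dim(mv), file.path(out_dir, paste0(ev, "_ventral_roi.png")))
    rows[[ev]] <- pair_views(rd, rv, di, vi, event_id = ev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  hash <- .config_hash(list(image_dir = image_dir, resolution = resolution,
                            min_area_px = min_area_px))
  path <- file.path(out_dir, "features_extracted.csv")
  .write_with_meta(out, path, seed, hash)
  invisible(path)
}

#' Run an experiment from files and write report CSVs
#'
#' File-level wrapper over [run_experiment()]: reads feature, taxonomy and
#' pool CSVs, runs the experiment, and writes tidy metric CSVs
#' (per-repeat and summary), local and novel tables, and the averaged
#' confusion matrix.
#'
#' @param features_csv,taxonomy_csv,pools_csv input paths.
#' @param out_dir output directory.
#' @param ... passed to [run_experiment()].
#' @param seed global seed.
#' @return The `evaluation_report`, invisibly.
#' @export
run_experiment_files <- function(features_csv, taxonomy_csv, pools_csv,
                                 out_dir = ".", seed = 1, ...) {
  table <- utils::read.csv(features_csv, stringsAsFactors = FALSE,
                           check.names = FALSE)
  tax <- load_taxonomy(taxonomy_csv)
  pools <- utils::read.csv(pools_csv, stringsAsFactors = FALSE)
  rep <- run_experiment(table, tax, pools, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(list(features = features_csv, seed = seed))
  .write_with_meta(rep$metrics, file.path(out_dir, "metrics.csv"), seed, hash)
  .write_with_meta(rep$summary, file.path(out_dir, "summary.csv"), seed, hash)
  if (!is.null(rep$local))
    .write_with_meta(rep$local, file.path(out_dir, "local.csv"), seed, hash)
  if (!is.null(rep$novel))
    .write_with_meta(rep$novel, file.path(out_dir, "novel.csv"), seed, hash)
  if (!is.null(rep$confusion))
    utils::write.csv(rep$confusion$mean,
                     file.path(out_dir, "confusion_lda.csv"))
  invisible(rep)
}
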