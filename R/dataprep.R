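# Data preparation: rare-species filtering, repeated 70:30 holdout splits,
# and z-score standardization with parameters fit on the training rows.

#' Validate a feature table
#'
#' Checks the table has the 68 canonical feature columns with no missing
#' values, a `species` column, and (optionally) that all species appear in
#' the taxonomy.
#'
#' @param table data.frame of specimens.
#' @param tax optional `taxonomy_table` to validate species against.
#' @return The table, invisibly, or an error.
#' @export
validate_feature_table <- function(table, tax = NULL) {
  feats <- feature_manifest()
  missing_cols <- setdiff(c("species", feats), names(table))
  if (length(missing_cols) > 0)
    stop("feature table is missing columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) ", ...")
  if (anyNA(table[, feats]))
    stop("feature table contains missing feature values")
  if (!is.null(tax)) {
    unknown <- setdiff(unique(table$species), tax$table[[tax$ranks[1]]])
    if (length(unknown) > 0)
      stop("species not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  invisible(table)
}

#' Separate rare species from the trainable dataset
#'
#' Species with fewer than `min_obs` observations (default: 30 or fewer)
#' are moved to the rare partition; they are excluded from training and
#' later used for novel-species evaluation. The partition is exhaustive
#' and disjoint.
#'
#' @param table a feature table with a `species` column.
#' @param min_obs minimum observations for a species to be trainable.
#' @return List with `common` and `rare` data.frames.
#' @export
filter_rare <- function(table, min_obs = 31) {
  counts <- table(table$species)
  common_sp <- names(counts)[counts >= min_obs]
  if (length(common_sp) == 0)
    stop("no species reaches ", min_obs,
         " observations; nothing is trainable")
  is_common <- table$species %in% common_sp
  list(common = table[is_common, , drop = FALSE],
       rare = table[!is_common, , drop = FALSE])
}

#' Repeated random train/test splits
#'
#' Simple (non-stratified) random sampling: each repeat draws
#' `round(ratio * n)` training rows; the remainder tests. Non-stratified
#' sampling means per-repeat species counts vary, and a species can drop
#' out of a training split entirely (recorded as a warning attribute).
#'
#' @param table a feature table.
#' @param ratio training fraction (default 0.7).
#' @param n_repeats number of repeats (default 10).
#' @param seed integer seed.
#' @param stratify if TRUE, sample within species instead.
#' @return List of splits; each has `train`, `test` (row indices),
#'   `repeat_index`, and `missing_species` (species absent from training).
#' @export
make_splits <- function(table, ratio = 0.7, n_repeats = 10, seed = 1,
                        stratify = FALSE) {
  n <- nrow(table)
  stopifnot(n >= 2, ratio > 0, ratio < 1, n_repeats >= 1)
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    if (stratify) {
      train <- unlist(lapply(split(seq_len(n), table$species), function(ix) {
        k <- max(1L, round(ratio * length(ix)))
        if (length(ix) == 1) ix else sample(ix, k)
      }), use.names = FALSE)
      train <- sort(train)
    } else {
      train <- sort(sample.int(n, round(ratio * n)))
    }
    test <- setdiff(seq_len(n), train)
    missing <- setdiff(unique(table$species), unique(table$species[train]))
    if (length(missing) > 0)
      warning(sprintf("repeat %d: species absent from training: %s",
                      r, paste(missing, collapse = ", ")))
    list(repeat_index = r, train = train, test = test,
         missing_species = missing)
  })
}

#' Standardize a split's features
#'
#' Computes per-feature mean and standard deviation on the training rows
#' and applies the z-score transform to both partitions (center and scale).
#' A zero-variance feature is centered and its sd treated as 1, with a
#' warning. By default parameters are fit on the training rows only; set
#' `fit_on = "combined"` to fit on train and test pooled.
#'
#' @param table the feature table the split indexes into.
#' @param split one element of [make_splits()].
#' @param fit_on "train" (default) or "combined".
#' @return List with `train`, `test` (standardized feature matrices),
#'   `train_labels`, `test_labels`, `center`, `scale`, and the split
#'   bookkeeping fields.
#' @export
standardize <- function(table, split, fit_on = c("train", "combined")) {
  fit_on <- match.arg(fit_on)
  feats <- feature_manifest()
  X <- as.matrix(table[, feats])
  fit_rows <- if (fit_on == "train") split$train else c(split$train, split$test)
  center <- colMeans(X[fit_rows, , drop = FALSE])
  scale_ <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
  zero <- !is.finite(scale_) | scale_ == 0
  if (any(zero)) {
    warning("zero-variance feature(s) pass through centered only: ",
            paste(feats[zero], collapse = ", "))
    scale_[zero] <- 1
  }
  z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  list(repeat_index = split$repeat_index,
       train = z[split$train, , drop = FALSE],
       test = z[split$test, , drop = FALSE],
       train_labels = table$species[split$train],
       test_labels = table$species[split$test],
       train_rows = split$train, test_rows = split$test,
       center = center, scale = scale_, fit_on = fit_on)
}

#' Invert a standardization
#' @param z standardized matrix.
#' @param std a standardized split carrying `center` and `scale`.
#' @return Matrix on the original feature scale.
#' @export
unstandardize <- function(z, std) {
  sweep(sweep(z, 2, std$scale, "*"), 2, std$center, "+")
}
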