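# Evaluation protocols: top-k accuracy and macro-averaged
# precision/recall/F1 at every taxonomic rank (hierarchical lifting of
# species-level predictions), single-level classifiers trained per rank,
# local species-pool reranking, novel-species scoring at measurable ranks,
# and repeat-averaged confusion matrices.

#' Top-k accuracy
#'
#' Fraction of specimens whose true label is among the k
#' highest-probability classes, with the deterministic tie-break of
#' [ranked_classes()].
#'
#' @param preds a `prediction_matrix`.
#' @param truth character vector of true labels, one per row.
#' @param k number of top classes to consider; clamped (with a warning) to
#'   the number of classes.
#' @return Accuracy in \[0, 1\].
#' @export
topk_accuracy <- function(preds, truth, k = 1) {
  stopifnot(nrow(preds) == length(truth), k >= 1)
  if (k > ncol(preds)) {
    warning(sprintf("k = %d exceeds the %d classes; clamped", k, ncol(preds)))
    k <- ncol(preds)
  }
  rk <- ranked_classes(preds, k)
  mean(vapply(seq_along(truth), function(i) truth[i] %in% rk[i, ],
              logical(1)))
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision (tp / (tp + fp)), recall (tp / (tp + fn)) and F1
#' (harmonic mean) from the confusion matrix, averaged without class
#' weighting. A class never predicted has precision 0; a class whose F1
#' denominator is 0 has F1 = 0. By default the class set is the union of
#' classes present in truth or predictions.
#'
#' @param pred character vector of top-1 predicted labels.
#' @param truth character vector of true labels.
#' @param classes class set to average over.
#' @return Named numeric vector: precision, recall, f1.
#' @export
macro_prf <- function(pred, truth, classes = sort(union(pred, truth))) {
  stopifnot(length(pred) == length(truth))
  per <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  c(precision = mean(per[1, ]), recall = mean(per[2, ]), f1 = mean(per[3, ]))
}

# top-k hit indicator at a lifted rank: the k species-level predictions are
# lifted and de-duplicated in rank order before counting k distinct taxa
.lifted_topk_hits <- function(rk_species, lifted_truth, rank, tax, k) {
  n <- nrow(rk_species)
  vapply(seq_len(n), function(i) {
    lifted <- lift_labels(rk_species[i, ], rank, tax)
    lifted_truth[i] %in% unique(lifted)[seq_len(min(k, length(unique(lifted))))]
  }, logical(1))
}

#' Hierarchical evaluation of species-level predictions
#'
#' Lifts species-level predictions and truth to every rank of the taxonomy
#' and computes top-1/top-3 accuracy and macro precision/recall/F1 at each.
#' A top-k hit at a lifted rank counts if any of the k top species-level
#' predictions lifts to the true label at that rank (duplicate lifted
#' labels collapse before counting k).
#'
#' @param preds species-level `prediction_matrix`.
#' @param truth species-level true labels.
#' @param tax a `taxonomy_table`.
#' @param ranks ranks to evaluate (default: all).
#' @return data.frame: rank, metric, value.
#' @export
hierarchical_evaluate <- function(preds, truth, tax, ranks = tax$ranks) {
  kmax <- min(3, ncol(preds))
  rk <- ranked_classes(preds, kmax)
  out <- list()
  for (r in ranks) {
    lt <- lift_labels(truth, r, tax)
    lp1 <- lift_labels(rk[, 1], r, tax)
    top1 <- mean(lp1 == lt)
    top3 <- mean(.lifted_topk_hits(rk, lt, r, tax, 3))
    prf <- macro_prf(lp1, lt)
    out[[r]] <- data.frame(
      rank = r,
      metric = c("top1", "top3", "precision", "recall", "f1"),
      value = c(top1, top3, prf[["precision"]], prf[["recall"]], prf[["f1"]]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Single-level evaluation: one model per rank
#'
#' Relabels the training data at each requested rank, trains a fresh model
#' per split repeat, and scores it only at that rank. At the species rank
#' this coincides with the hierarchical classifier by construction. A rank
#' with a single class yields trivially perfect metrics and is flagged in
#' the output.
#'
#' @param spec a `model_spec`.
#' @param table the feature table splits index into.
#' @param splits list from [make_splits()].
#' @param tax a `taxonomy_table`.
#' @param ranks ranks to evaluate.
#' @param fit_on standardization mode, see [standardize()].
#' @return data.frame: rank, repeat_index, metric, value, single_class.
#' @export
single_level_evaluate <- function(spec, table, splits, tax,
                                  ranks = tax$ranks, fit_on = "train") {
  out <- list()
  for (s in splits) {
    std <- standardize(table, s, fit_on = fit_on)
    for (r in ranks) {
      ytr <- lift_labels(std$train_labels, r, tax)
      yte <- lift_labels(std$test_labels, r, tax)
      single <- length(unique(ytr)) < 2
      if (single) {
        vals <- c(top1 = 1, top3 = 1, precision = 1, recall = 1, f1 = 1)
      } else {
        m <- train_model(spec, std$train, ytr,
                         validation = list(x = std$test, y = yte))
        pr <- predict_proba(m, std$test)
        prf <- macro_prf(top1_labels(pr), yte)
        vals <- c(top1 = topk_accuracy(pr, yte, 1),
                  top3 = suppressWarnings(topk_accuracy(pr, yte, 3)),
                  prf)
      }
      out[[length(out) + 1]] <- data.frame(
        rank = r, repeat_index = s$repeat_index,
        metric = names(vals), value = as.numeric(vals),
        single_class = single, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Restrict predictions to local species pools
#'
#' Removes classes outside each specimen's site pool and reranks the
#' remainder by their original probabilities (renormalized for reporting).
#' Rows where every pooled class has probability 0 fall back to ranking by
#' training-class frequency within the pool. Sites whose pool, intersected
#' with the model's classes, holds a single species are guaranteed perfect
#' accuracy, so they are excluded from the pooled local accuracy.
#'
#' @param preds species-level `prediction_matrix`.
#' @param sites character vector of specimen site ids.
#' @param pools data.frame `site_id`, `species` (one pair per row).
#' @param truth true species labels (for accuracies); optional.
#' @return List: `preds` (reranked `prediction_matrix`), `per_site`
#'   (site, n, pool size, accuracy, singleton flag), `local_accuracy`
#'   (pooled top-1 over non-singleton sites), `unrestricted_accuracy`.
#' @export
local_filter <- function(preds, sites, pools, truth = NULL) {
  stopifnot(nrow(preds) == length(sites))
  classes <- colnames(preds)
  freq <- attr(preds, "class_freq")
  missing_sites <- setdiff(unique(sites), unique(pools$site_id))
  if (length(missing_sites) > 0)
    stop("site(s) absent from the pool table: ",
         paste(missing_sites, collapse = ", "))
  pool_of <- split(pools$species, pools$site_id)
  p <- unclass(preds)
  for (i in seq_len(nrow(p))) {
    pool <- intersect(pool_of[[sites[i]]], classes)
    if (length(pool) == 0)
      stop("site ", sites[i], " has no pooled species among the model classes")
    outside <- setdiff(classes, pool)
    p[i, outside] <- 0
    tot <- sum(p[i, ])
    if (tot > 0) {
      p[i, ] <- p[i, ] / tot
    } else {
      # deterministic fallback: training frequency among the pool
      p[i, pool] <- freq[pool] / sum(freq[pool])
    }
  }
  filtered <- structure(p, class_freq = freq,
                        class = c("prediction_matrix", "matrix", "array"))
  per_site <- NULL
  local_acc <- NA_real_
  unrestricted <- NA_real_
  if (!is.null(truth)) {
    pred1 <- top1_labels(filtered)
    unrestricted <- topk_accuracy(preds, truth, 1)
    site_ids <- sort(unique(sites))
    per_site <- do.call(rbind, lapply(site_ids, function(sid) {
      ix <- sites == sid
      pool <- intersect(pool_of[[sid]], classes)
      data.frame(site_id = sid, n = sum(ix),
                 pool_size = length(pool),
                 singleton = length(pool) == 1,
                 accuracy = mean(pred1[ix] == truth[ix]),
                 stringsAsFactors = FALSE)
    }))
    keep <- sites %in% per_site$site_id[!per_site$singleton]
    local_acc <- if (any(keep)) mean(pred1[keep] == truth[keep]) else NA_real_
  }
  list(preds = filtered, per_site = per_site,
       local_accuracy = local_acc, unrestricted_accuracy = unrestricted)
}

#' Novel-species evaluation at measurable ranks
#'
#' Rare species never seen in training are forced through the species-level
#' model; predictions are lifted rank by rank. A rank is measurable for a
#' specimen only when its true label at that rank is shared with at least
#' one training species (the novel species belongs to a clade the model
#' knows). Accuracy is computed over measurable specimens per rank.
#'
#' @param model a `pitfall_model` trained on the common species.
#' @param x standardized feature matrix of the rare specimens.
#' @param species true species labels of the rare specimens (must be in
#'   the taxonomy, absent from the model classes).
#' @param tax a `taxonomy_table`.
#' @return data.frame: rank, n_measurable, accuracy (NA when no specimen
#'   is measurable at that rank).
#' @export
novel_species_evaluate <- function(model, x, species, tax) {
  unknown <- setdiff(unique(species), tax$table[[tax$ranks[1]]])
  if (length(unknown) > 0)
    stop("rare species missing from taxonomy: ",
         paste(unknown, collapse = ", "))
  overlap <- intersect(unique(species), model$classes)
  if (length(overlap) > 0)
    stop("species present in the model classes are not novel: ",
         paste(overlap, collapse = ", "))
  preds <- predict_proba(model, x)
  pred_sp <- top1_labels(preds)
  out <- lapply(tax$ranks, function(r) {
    truth_r <- lift_labels(species, r, tax)
    train_r <- unique(lift_labels(model$classes, r, tax))
    measurable <- truth_r %in% train_r
    acc <- if (any(measurable)) {
      mean(lift_labels(pred_sp[measurable], r, tax) == truth_r[measurable])
    } else NA_real_
    data.frame(rank = r, n_measurable = sum(measurable), accuracy = acc,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Repeat-averaged confusion matrix
#'
#' Cell-wise average of per-repeat confusion matrices. Rows are predicted
#' labels, columns actual labels; an "Actual" column margin and
#' "Predicted" row margin give average per-class test counts. The
#' `percent` element reports cells as percentages of their column totals.
#'
#' @param pred_list list of per-repeat predicted label vectors.
#' @param truth_list list of per-repeat true label vectors.
#' @param classes class set (default: union over repeats).
#' @return List: `mean` (matrix with margins), `percent`.
#' @export
confusion_matrix_avg <- function(pred_list, truth_list,
                                 classes = NULL) {
  stopifnot(length(pred_list) == length(truth_list))
  if (is.null(classes))
    classes <- sort(unique(c(unlist(pred_list), unlist(truth_list))))
  mats <- Map(function(p, t) {
    table(factor(p, classes), factor(t, classes))
  }, pred_list, truth_list)
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  col_tot <- colSums(avg)
  pct <- sweep(avg, 2, ifelse(col_tot > 0, col_tot, 1), "/") * 100
  with_margins <- rbind(cbind(avg, Predicted = rowSums(avg)),
                        Actual = c(col_tot, sum(avg)))
  list(mean = with_margins, percent = pct)
}
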