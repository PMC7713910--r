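# Brute-force metric oracles live in helper-oracles.R.

test_that("top-k accuracy matches hand-ranked examples and the superset rule", {
  classes <- c("a", "b", "c", "d")
  probs <- rbind(c(0.7, 0.2, 0.06, 0.04),
                 c(0.3, 0.4, 0.2, 0.1),
                 c(0.4, 0.3, 0.2, 0.1))
  p <- pm(probs, classes)
  truth <- c("a", "a", "d")  # ranks 1, 2, 4
  expect_equal(topk_accuracy(p, truth, 1), 1 / 3)
  expect_equal(topk_accuracy(p, truth, 3), 2 / 3)
  expect_equal(topk_accuracy(p, truth, 4), 1)
  expect_warning(acc <- topk_accuracy(p, truth, 10), "clamped")
  expect_equal(acc, 1)
  expect_gte(topk_accuracy(p, truth, 3), topk_accuracy(p, truth, 1))
})

test_that("macro precision/recall/F1 match hand computation on a 2x2 case", {
  # confusion [[8,2],[3,7]]: pred A truth A 8, pred A truth B 2, ...
  pred <- c(rep("A", 8), rep("A", 2), rep("B", 3), rep("B", 7))
  truth <- c(rep("A", 8), rep("B", 2), rep("A", 3), rep("B", 7))
  got <- macro_prf(pred, truth)
  expect_equal(got[["precision"]], (8 / 10 + 7 / 10) / 2)
  expect_equal(got[["recall"]], (8 / 11 + 7 / 9) / 2)
  pa <- 8 / 10; ra <- 8 / 11; pb <- 7 / 10; rb <- 7 / 9
  expect_equal(got[["f1"]],
               (2 * pa * ra / (pa + ra) + 2 * pb * rb / (pb + rb)) / 2)
  expect_equal(macro_prf(c("a", "b"), c("a", "b")),
               c(precision = 1, recall = 1, f1 = 1))
})

test_that("metrics equal brute-force oracles on 100 random 5-class sets", {
  classes <- paste0("c", 1:5)
  for (seed in 1:100) {
    set.seed(seed)
    n <- 40
    probs <- matrix(rexp(n * 5), n, 5)
    probs <- probs / rowSums(probs)
    truth <- sample(classes, n, replace = TRUE)
    p <- pm(probs, classes)
    pred <- top1_labels(p)
    expect_equal(macro_prf(pred, truth, classes),
                 oracle_prf(pred, truth, classes))
    # probabilities are continuous: no ties, so the oracle's plain ordering
    # agrees with the package tie-break
    for (k in c(1, 3))
      expect_equal(topk_accuracy(p, truth, k), oracle_topk(p, truth, k))
  }
})

test_that("hierarchical lifting scores the worked misidentification examples", {
  tax <- examples_taxonomy()
  classes <- c("Pasimachus strenuus", "Pasimachus californicus",
               "Scarites subterraneus", "Cyclotrachelus torvus")
  # P. strenuus predicted as P. californicus: species wrong, genus right
  probs <- rbind(c(0.1, 0.8, 0.06, 0.04),
                 c(0.05, 0.05, 0.1, 0.8))
  p <- pm(probs, classes)
  truth <- c("Pasimachus strenuus",   # -> predicted congener
             "Scarites subterraneus") # -> predicted Cyclotrachelus torvus
  h <- hierarchical_evaluate(p, truth, tax)
  top1 <- function(r) h$value[h$rank == r & h$metric == "top1"]
  # row 1 correct from genus up; row 2 wrong at every rank
  expect_equal(top1("species"), 0)
  expect_equal(top1("group"), 0)
  expect_equal(top1("genus"), 0.5)
  expect_equal(top1("subtribe"), 0.5)
  expect_equal(top1("tribe"), 0.5)
  expect_equal(top1("subfamily"), 0.5)
})

test_that("hierarchical top-1 is monotone in rank and top-3 >= top-1", {
  for (seed in 1:5) {
    cfg <- synthetic_preset("reduced", seed = seed, n_specimens = 300)
    ds <- make_synthetic_dataset(cfg)
    parts <- filter_rare(ds$table, min_obs = 15)
    s <- suppressWarnings(make_splits(parts$common, n_repeats = 1,
                                      seed = seed))[[1]]
    std <- standardize(parts$common, s)
    m <- train_model(model_spec("lda"), std$train, std$train_labels)
    h <- hierarchical_evaluate(predict_proba(m, std$test), std$test_labels,
                               ds$taxonomy)
    top1 <- h$value[h$metric == "top1"][match(ds$taxonomy$ranks,
                                              h$rank[h$metric == "top1"])]
    expect_true(all(diff(top1) >= -1e-12))
    expect_true(all(h$value[h$metric == "top3"] >=
                      h$value[h$metric == "top1"] - 1e-12))
    expect_true(all(h$value >= 0 & h$value <= 1))
  }
})

test_that("local-pool reranking restricts, renormalizes, and never demotes truth in pool", {
  classes <- c("Chlaenius aestivus", "Cyclotrachelus furtivus",
               "Pasimachus strenuus")
  probs <- rbind(c(0.2, 0.3, 0.5),
                 c(0.6, 0.1, 0.3))
  p <- pm(probs, classes, freq = c(0.5, 0.3, 0.2))
  pools <- data.frame(
    site_id = c("s1", "s1", "s2"),
    species = c("Chlaenius aestivus", "Cyclotrachelus furtivus",
                "Pasimachus strenuus"))
  truth <- c("Cyclotrachelus furtivus", "Pasimachus strenuus")
  lf <- local_filter(p, c("s1", "s2"), pools, truth = truth)
  # row 1 restricted to the two pooled species, renormalized
  expect_equal(unname(lf$preds[1, ]), c(0.4, 0.6, 0))
  # row 2: singleton pool forces the only candidate
  expect_equal(unname(lf$preds[2, ]), c(0, 0, 1))
  ps <- lf$per_site
  expect_true(ps$singleton[ps$site_id == "s2"])
  expect_equal(ps$accuracy[ps$site_id == "s2"], 1)
  # pooled local accuracy excludes the singleton site
  expect_equal(lf$local_accuracy, 1)  # row 1 reranked to the true species

  expect_error(local_filter(p, c("s1", "s9"), pools), "absent from the pool")

  # property: truth in pool implies local top-1 >= unrestricted top-1
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    cls <- paste0("sp", 1:6)
    pr <- matrix(rexp(n * 6), n, 6); pr <- pr / rowSums(pr)
    tr <- sample(cls, n, replace = TRUE)
    sites <- sample(c("x", "y"), n, replace = TRUE)
    pool <- rbind(data.frame(site_id = "x", species = cls[1:4]),
                  data.frame(site_id = "y", species = cls[3:6]))
    keep <- (sites == "x" & tr %in% cls[1:4]) |
      (sites == "y" & tr %in% cls[3:6])
    pmat <- pm(pr[keep, ], cls)
    lf <- local_filter(pmat, sites[keep], pool, truth = tr[keep])
    expect_gte(topk_accuracy(lf$preds, tr[keep], 1),
               topk_accuracy(pmat, tr[keep], 1))
  }
})

test_that("all-zero pooled probabilities fall back to training frequency", {
  classes <- c("a", "b", "c")
  p <- pm(rbind(c(1, 0, 0)), classes, freq = c(0.5, 0.2, 0.3))
  pools <- data.frame(site_id = "s", species = c("b", "c"))
  lf <- local_filter(p, "s", pools)
  expect_equal(unname(lf$preds[1, ]), c(0, 0.4, 0.6))
})

test_that("novel species score only at measurable ranks (worked example)", {
  tax <- examples_taxonomy()
  # training classes include a congener of the novel species and the
  # predicted species
  xtr <- matrix(c(0, 0.2, 5, 5.2, 10, 10.2), ncol = 1,
                dimnames = list(NULL, "f"))
  ytr <- c("Pterostichus commutabilis", "Pterostichus commutabilis",
           "Cyclotrachelus furtivus", "Cyclotrachelus furtivus",
           "Chlaenius aestivus", "Chlaenius aestivus")
  m <- train_model(model_spec("knn", grid = 1L), xtr, ytr)
  # a novel Pterostichus trinarius specimen that lands on C. furtivus
  xnov <- matrix(5.1, 1, 1, dimnames = list(NULL, "f"))
  nv <- novel_species_evaluate(m, xnov, "Pterostichus trinarius", tax)
  row <- function(r) nv[nv$rank == r, ]
  # species and group unmeasurable (no shared clade in training)
  expect_equal(row("species")$n_measurable, 0)
  expect_true(is.na(row("species")$accuracy))
  expect_equal(row("group")$n_measurable, 0)
  # genus measurable (P. commutabilis trains) but prediction wrong
  expect_equal(row("genus")$accuracy, 0)
  # subtribe Pterostichini shared with the prediction: correct
  expect_equal(row("subtribe")$accuracy, 1)
  expect_equal(row("tribe")$accuracy, 1)
  expect_equal(row("subfamily")$accuracy, 1)

  expect_error(novel_species_evaluate(m, xnov, "Amara aenea", tax),
               "missing from taxonomy")
  expect_error(novel_species_evaluate(m, xnov, "Chlaenius aestivus", tax),
               "not novel")
})

test_that("confusion matrices average cell-wise with conserved margins", {
  # perfect predictor: diagonal, column sums = class counts
  p1 <- c("a", "a", "b"); t1 <- p1
  cm <- confusion_matrix_avg(list(p1), list(t1))
  expect_equal(unname(cm$mean["a", "a"]), 2)
  expect_equal(unname(cm$mean["b", "b"]), 1)
  expect_equal(unname(cm$mean["a", "b"]), 0)

  # average of two hand-built 2x2 matrices
  pa <- c("a", "a", "b", "b"); ta <- c("a", "b", "a", "b")
  pb <- c("a", "b", "b", "b"); tb <- c("a", "a", "b", "b")
  cm2 <- confusion_matrix_avg(list(pa, pb), list(ta, tb))
  # cell (a, a): repeat 1 has 1, repeat 2 has 1 -> mean 1
  expect_equal(unname(cm2$mean["a", "a"]), 1)
  # cell (b, a): repeat 1 has 1, repeat 2 has 1 -> 1
  expect_equal(unname(cm2$mean["b", "a"]), 1)
  # column sums equal average per-repeat truth counts
  expect_equal(unname(cm2$mean["Actual", "a"]), 2)
  expect_equal(unname(cm2$mean["Actual", "b"]), 2)
  # percentages are column-normalized
  expect_equal(unname(colSums(cm2$percent)), c(100, 100))
})
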