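# Independent brute-force / closed-form oracles. These share no code with
# the package's metric or classifier paths.

oracle_prf <- function(pred, truth, classes) {
  precs <- recs <- f1s <- numeric(0)
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    precs <- c(precs, p); recs <- c(recs, r)
    f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  c(precision = mean(precs), recall = mean(recs), f1 = mean(f1s))
}

oracle_topk <- function(probs, truth, k) {
  hits <- 0
  for (i in seq_len(nrow(probs))) {
    ord <- order(probs[i, ], decreasing = TRUE)
    if (truth[i] %in% colnames(probs)[ord[seq_len(k)]]) hits <- hits + 1
  }
  hits / nrow(probs)
}

bayes_lda_posterior <- function(x, mu, sigma2, prior) {
  # shared-variance Gaussian classes, 1-D
  ll <- vapply(seq_along(mu), function(c)
    dnorm(x, mu[c], sqrt(sigma2)) * prior[c], numeric(length(x)))
  ll / rowSums(ll)
}

bayes_nb_posterior <- function(x, mu, sd_, prior) {
  # x: n x p; mu, sd_: classes x p
  n <- nrow(x)
  post <- matrix(0, n, nrow(mu))
  for (c in seq_len(nrow(mu))) {
    l <- rep(log(prior[c]), n)
    for (j in seq_len(ncol(x)))
      l <- l + dnorm(x[, j], mu[c, j], sd_[c, j], log = TRUE)
    post[, c] <- l
  }
  post <- exp(post - apply(post, 1, max))
  post / rowSums(post)
}
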