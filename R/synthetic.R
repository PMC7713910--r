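# Synthetic multi-site specimen datasets with known ground truth: a nested
# taxonomy, class-conditional Gaussian feature vectors whose means drift
# down the taxonomy (so congeners are more alike than cross-tribe species),
# skewed species abundances, and small per-site species pools.

#' Synthetic dataset configuration
#'
#' The default configuration emulates the shape of a continental pitfall
#' survey season: 3,270 specimens of 64 species in 32 genera, 19 tribes and
#' 8 subfamilies, spread over 18 sites, with a geometric abundance law
#' skewed so that roughly 60% of species fall at 30 or fewer observations.
#' `synthetic_preset("reduced")` gives a small preset used for fast
#' experimentation (about 600 specimens, 12 species, 12 sites).
#'
#' @param n_specimens total number of specimens.
#' @param rank_counts named integer vector of taxon counts per rank, most
#'   specific first; must be non-increasing upward.
#' @param drift per-rank standard deviation of the mean-drift random walk
#'   down the taxonomy (class separation; 0 = no signal).
#' @param within_sd within-species feature standard deviation.
#' @param abundance_ratio geometric abundance decay ratio in (0, 1); the
#'   i-th most common species has expected abundance proportional to
#'   `abundance_ratio^(i-1)`.
#' @param n_sites number of collection sites.
#' @param pool_range allowed species-pool sizes per site, `c(min, max)`.
#' @param pool_mean target mean pool size.
#' @param seed integer seed fixing all randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_specimens = 3270,
                             rank_counts = c(species = 64, group = 48,
                                             genus = 32, subtribe = 24,
                                             tribe = 19, subfamily = 8),
                             drift = 0.2,
                             within_sd = 1,
                             abundance_ratio = 0.9,
                             n_sites = 18,
                             pool_range = c(1, 7),
                             pool_mean = 3,
                             seed = 1) {
  stopifnot(n_specimens >= 1, length(rank_counts) >= 1,
            all(rank_counts >= 1), drift >= 0, within_sd >= 0,
            abundance_ratio > 0, abundance_ratio < 1,
            n_sites >= 1, length(pool_range) == 2,
            pool_range[1] >= 1, pool_range[1] <= pool_range[2],
            pool_mean >= pool_range[1], pool_mean <= pool_range[2])
  if (is.null(names(rank_counts)))
    names(rank_counts) <- DEFAULT_RANKS[seq_along(rank_counts)]
  if (any(diff(rank_counts) > 0))
    stop("rank_counts must be non-increasing from species upward")
  structure(list(n_specimens = as.integer(n_specimens),
                 rank_counts = rank_counts,
                 drift = drift, within_sd = within_sd,
                 abundance_ratio = abundance_ratio,
                 n_sites = as.integer(n_sites),
                 pool_range = as.integer(pool_range),
                 pool_mean = pool_mean,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Named synthetic presets
#'
#' `"emulation"` mirrors the full survey shape (3,270 specimens, 64
#' species, 18 sites); `"reduced"` is a small preset (600 specimens, 12
#' species, 12 sites) sized for fast runs.
#'
#' @param name "emulation" or "reduced".
#' @param seed seed passed through to [synthetic_config()].
#' @param ... overrides for individual config fields.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("reduced", "emulation"), seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(name,
    emulation = synthetic_config(seed = seed),
    reduced = synthetic_config(
      n_specimens = 600,
      rank_counts = c(species = 12, group = 11, genus = 8, subtribe = 6,
                      tribe = 5, subfamily = 3),
      abundance_ratio = 0.78,
      n_sites = 12,
      seed = seed))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  do.call(synthetic_config, unclass(base))
}

#' Generate a nested synthetic taxonomy
#'
#' Builds a taxonomy with the configured number of taxa at each rank by
#' assigning each taxon a random parent at the rank above (every parent is
#' guaranteed at least one child). The result passes the same validation
#' as [load_taxonomy()].
#'
#' @param config a `synthetic_config`.
#' @return A `taxonomy_table`.
#' @export
make_taxonomy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  counts <- config$rank_counts
  ranks <- names(counts)
  set.seed(config$seed)
  prefix <- substr(ranks, 1, 3)
  labels <- lapply(seq_along(ranks), function(i)
    sprintf("%s%03d", prefix[i], seq_len(counts[i])))
  # parent map per rank boundary: child j at rank i -> parent at rank i+1.
  # Random surjection: the first n_parent children (shuffled) take distinct
  # parents, the rest draw uniformly.
  maps <- list()
  for (i in seq_len(length(ranks) - 1)) {
    nc <- counts[i]; np <- counts[i + 1]
    parent <- integer(nc)
    shuffled <- sample.int(nc)
    parent[shuffled[seq_len(np)]] <- sample.int(np)
    rest <- shuffled[-seq_len(np)]
    if (length(rest) > 0) parent[rest] <- sample.int(np, length(rest), replace = TRUE)
    maps[[i]] <- parent
  }
  rows <- data.frame(labels[[1]], stringsAsFactors = FALSE)
  idx <- seq_len(counts[1])
  for (i in seq_len(length(ranks) - 1)) {
    idx <- maps[[i]][idx]
    rows <- cbind(rows, labels[[i + 1]][idx], stringsAsFactors = FALSE)
  }
  names(rows) <- ranks
  taxonomy_table(rows)
}

# Expected species abundances under the geometric law, integerized to sum
# to n with a minimum of 1 per species.
.abundances <- function(n, n_species, ratio) {
  w <- ratio^(seq_len(n_species) - 1)
  counts <- pmax(1L, round(n * w / sum(w)))
  # adjust to the exact total on the most common species
  counts[1] <- counts[1] + (n - sum(counts))
  if (counts[1] < 1) stop("n_specimens too small for the species count")
  counts
}

#' Sample a hierarchically structured feature table
#'
#' Draws per-species class-conditional Gaussian feature vectors in the 68
#' dimensions of [feature_manifest()]. Species means are built by a
#' random-walk drift down the taxonomy: each taxon's mean adds independent
#' Gaussian noise of sd `drift` to its parent's mean, so congeneric species
#' lie closer together than species from different tribes. Abundances
#' follow the configured geometric law.
#'
#' @param tax a `taxonomy_table` (typically from [make_taxonomy()]).
#' @param config a `synthetic_config`.
#' @return data.frame: `specimen_id`, `species`, then the 68 feature
#'   columns. Attribute `"species_means"` carries the true class means.
#' @export
sample_feature_table <- function(tax, config) {
  stopifnot(inherits(tax, "taxonomy_table"), inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  feats <- feature_manifest()
  p <- length(feats)
  ranks <- tax$ranks
  top <- rev(ranks)[1]
  # drift down the taxonomy, most general rank first
  means <- list()
  for (lbl in unique(tax$table[[top]]))
    means[[lbl]] <- stats::rnorm(p, 0, config$drift)
  for (i in rev(seq_len(length(ranks) - 1))) {
    child_rank <- ranks[i]; parent_rank <- ranks[i + 1]
    tab <- unique(tax$table[, c(child_rank, parent_rank)])
    for (j in seq_len(nrow(tab))) {
      child <- tab[j, 1]; parent <- tab[j, 2]
      if (is.null(means[[child]]))
        means[[child]] <- means[[parent]] + stats::rnorm(p, 0, config$drift)
    }
  }
  species <- tax$table[[ranks[1]]]
  counts <- .abundances(config$n_specimens, length(species),
                        config$abundance_ratio)
  lab <- rep(species, counts)
  X <- matrix(stats::rnorm(length(lab) * p, 0, config$within_sd),
              length(lab), p)
  M <- do.call(rbind, means[lab])
  X <- X + M
  colnames(X) <- feats
  out <- data.frame(specimen_id = sprintf("spec%05d", seq_along(lab)),
                    species = lab, X, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "species_means") <- do.call(rbind, means[species])
  out
}

#' Assign specimens to sites with local species pools
#'
#' Each site receives a species pool whose size is drawn within
#' `pool_range` around `pool_mean` (a shifted binomial), with common
#' species more likely to enter pools. Every species is guaranteed at
#' least one site, and each specimen is assigned uniformly among the sites
#' whose pool contains its species.
#'
#' @param table a feature table from [sample_feature_table()].
#' @param config a `synthetic_config`.
#' @return List with `table` (input plus a `site` column) and `pools`
#'   (data.frame `site_id`, `species`, one pair per row).
#' @export
assign_sites <- function(table, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  species <- unique(table$species)
  ns <- length(species)
  if (config$pool_range[1] > ns)
    stop("pool_range infeasible: fewer species than the minimum pool size")
  sites <- sprintf("site%02d", seq_len(config$n_sites))
  rng <- config$pool_range
  span <- rng[2] - rng[1]
  pr <- if (span > 0) (config$pool_mean - rng[1]) / span else 0
  freq <- table(factor(table$species, levels = species))
  w <- as.numeric(freq) / sum(freq)
  pools <- lapply(seq_len(config$n_sites), function(i) {
    size <- min(rng[1] + stats::rbinom(1, span, pr), ns)
    sample(species, size, prob = w)
  })
  # coverage fix-up: any species missing from all pools joins the site
  # with the smallest pool that still has room
  for (sp in species) {
    if (!any(vapply(pools, function(p) sp %in% p, logical(1)))) {
      sizes <- lengths(pools)
      open <- which(sizes < rng[2])
      if (length(open) == 0) open <- seq_along(pools)
      tgt <- open[which.min(sizes[open])]
      pools[[tgt]] <- c(pools[[tgt]], sp)
    }
  }
  site_of <- lapply(species, function(sp)
    which(vapply(pools, function(p) sp %in% p, logical(1))))
  names(site_of) <- species
  table$site <- vapply(table$species, function(sp) {
    cand <- site_of[[sp]]
    sites[if (length(cand) == 1) cand else sample(cand, 1)]
  }, character(1))
  pool_df <- do.call(rbind, lapply(seq_along(pools), function(i)
    data.frame(site_id = sites[i], species = pools[[i]],
               stringsAsFactors = FALSE)))
  list(table = table, pools = pool_df)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: taxonomy, feature table, and site pools from one
#' config, fully determined by `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return List with `taxonomy`, `table` (features + species + site), and
#'   `pools`.
#' @export
make_synthetic_dataset <- function(config = synthetic_preset("reduced")) {
  tax <- make_taxonomy(config)
  tab <- sample_feature_table(tax, config)
  st <- assign_sites(tab, config)
  list(taxonomy = tax, table = st$table, pools = st$pools, config = config)
}
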