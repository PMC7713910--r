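#' Shape of the reference carabid survey dataset
#'
#' The published totals of the continental pitfall survey season that the
#' synthetic emulation preset mirrors: specimen, taxon, site and
#' trapping-event counts, and the local species-pool statistics. These are
#' the inputs for dataset-scale summaries such as the mean number of
#' individuals per trapping event (`individuals / trapping_events`) and
#' the mean number of specimens per site (`individuals / sites`).
#'
#' @return Named list of counts: `individuals`, `trapping_events`,
#'   `sites`, `species`, `genera`, `tribes`, `subfamilies`,
#'   `pool_size_range`, `pool_size_mean`, `training_species`.
#' @export
study_shape <- function() {
  list(individuals = 3270L,
       trapping_events = 398L,
       sites = 18L,
       species = 64L,
       genera = 32L,
       tribes = 19L,
       subfamilies = 8L,
       pool_size_range = c(1L, 7L),
       pool_size_mean = 3,
       training_species = 25L)
}
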