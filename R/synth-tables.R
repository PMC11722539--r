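# Synthetic measurement-table generators: per-segment intensity tables for
# the two-reference normalization stage and integer count groups for the
# statistics module.

#' Generate a per-segment intensity measurement table
#'
#' Draws `n_per_group` Gaussian measurements about each group mean, labeled
#' by group and timepoint. Group labels follow the `genotype_timepoint`
#' convention (for example `wt_15`, `mutant_15`); the timepoint column is the
#' suffix after the final underscore.
#'
#' @param seed Integer seed.
#' @param group_means Named numeric vector of true group mean intensities.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_per_group Segments measured per group (>= 1).
#' @return A list with `table` (tibble `group, timepoint, segment_id,
#'   intensity`) and `truth` (class `ground_truth` holding `group_means`).
#' @export
#' @examples
#' generate_intensity_table(1, c(mutant_15 = 10, wt_15 = 110), 5, 26)$table
generate_intensity_table <- function(seed, group_means, noise_sd, n_per_group) {
  seed <- check_count(seed, "seed")
  check_number(noise_sd, "noise_sd", lower = 0)
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1L)
  if (is.null(names(group_means)) || any(!nzchar(names(group_means)))) {
    abort("`group_means` must be a named numeric vector.")
  }
  set.seed(seed)
  tab <- purrr::map_dfr(names(group_means), function(g) {
    tibble(
      group = g,
      timepoint = sub("^.*_", "", g),
      segment_id = seq_len(n_per_group),
      intensity = pmax(0, group_means[[g]] + rnorm(n_per_group, 0, noise_sd))
    )
  })
  truth <- structure(list(group_means = group_means,
                          params = list(seed = seed, noise_sd = noise_sd,
                                        n_per_group = n_per_group)),
                     class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Generate integer count groups
#'
#' Draws `n` Gaussian values about `mean`, rounds to the nearest integer and
#' clamps at zero; a fixture generator for count-comparison statistics such
#' as per-neuron filopodia numbers.
#'
#' @param seed Integer seed.
#' @param mean,sd Gaussian mean and standard deviation of the counts.
#' @param n Number of draws (>= 2).
#' @return Integer vector of length `n`.
#' @export
generate_group_counts <- function(seed, mean, sd, n) {
  seed <- check_count(seed, "seed")
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0)
  n <- check_count(n, "n", lower = 2L)
  set.seed(seed)
  pmax(0L, as.integer(round(rnorm(n, mean, sd))))
}
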