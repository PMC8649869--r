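#' Ground truth for a simulated RNA-seq experiment
#'
#' Describes per-gene baseline expression and per-group log2 effects. A
#' contrast between two groups has planted log2 fold change equal to the
#' difference of the two groups' effect columns, so effects can be shared or
#' private between knockdown conditions.
#'
#' @param baseline_mean Named numeric vector, gene -> expected count in the
#'   reference condition (> 0).
#' @param group_effects Numeric matrix, genes x groups, of log2 effects
#'   relative to baseline; 0 means unchanged in that group. Row names must
#'   equal `names(baseline_mean)`; column names are the group labels.
#' @return An `expression_truth` object.
#' @export
expression_truth <- function(baseline_mean, group_effects) {
  if (any(baseline_mean <= 0) || anyNA(baseline_mean))
    abort_validation("baseline_mean must be positive for every gene")
  if (!is.matrix(group_effects) || is.null(rownames(group_effects)) ||
      is.null(colnames(group_effects)))
    abort_validation("group_effects must be a named genes x groups matrix")
  if (!identical(rownames(group_effects), names(baseline_mean)))
    abort_validation("group_effects rows must match names(baseline_mean)")
  structure(list(baseline_mean = baseline_mean,
                 group_effects = group_effects),
            class = "expression_truth")
}

#' Planted log2 fold change of a contrast
#'
#' @param truth An `expression_truth`.
#' @param group_b,group_a Group labels; the contrast is B vs A.
#' @return Named numeric vector of planted log2 fold changes.
#' @export
de_effect <- function(truth, group_b, group_a) {
  stopifnot(inherits(truth, "expression_truth"))
  truth$group_effects[, group_b] - truth$group_effects[, group_a]
}

#' Simulate negative-binomial RNA-seq counts with planted effects
#'
#' Counts for gene g in group k are negative-binomial with mean
#' `baseline_mean[g] * 2^group_effects[g, k]` and dispersion `phi`
#' (variance = mu + phi * mu^2); `phi = 0` gives Poisson counts.
#'
#' @param truth An `expression_truth`.
#' @param n_replicates Replicates per group (>= 2).
#' @param dispersion Dispersion phi >= 0.
#' @param seed Integer seed.
#' @return A raw `count_matrix` whose sample table carries a `group` column.
#' @export
simulate_rnaseq <- function(truth, n_replicates = 3L, dispersion = 0.1,
                            seed = 1L) {
  stopifnot(inherits(truth, "expression_truth"))
  if (dispersion < 0) abort_parameter("dispersion must be >= 0")
  if (!is_count(n_replicates) || n_replicates < 2)
    abort_parameter("n_replicates must be an integer >= 2")
  groups <- colnames(truth$group_effects)
  genes <- names(truth$baseline_mean)
  with_seed(seed, {
    cols <- list()
    samp <- list()
    for (k in groups) {
      mu <- truth$baseline_mean * 2^truth$group_effects[, k]
      for (r in seq_len(n_replicates)) {
        y <- if (dispersion <= 0) stats::rpois(length(mu), mu)
             else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        id <- sprintf("%s_rep%d", k, r)
        cols[[id]] <- y
        samp[[id]] <- data.frame(sample = id, group = k, replicate = r,
                                 stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    count_matrix(m, samples = do.call(rbind, samp))
  })
}
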