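#' Median-of-ratios size factors
#'
#' Library-size normalization for RNA-seq counts: a pseudo-reference sample
#' is built as the per-gene geometric mean over genes expressed in every
#' sample; each sample's factor is the median of its ratios to that
#' reference, and factors are centered to geometric mean 1.
#'
#' @param cm A raw `count_matrix`.
#' @return Named numeric vector of positive per-sample scale factors.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    abort_validation(paste("no gene is positive in all samples;",
                           "filter low-coverage genes first"))
  sub <- m[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub / ref, 2, stats::median)
  sf <- sf / geometric_mean(sf)
  stats::setNames(sf, colnames(m))
}

#' Method-of-moments dispersion with shrinkage to the common value
#'
#' For each gene, a pooled within-group moment estimate of the
#' negative-binomial dispersion phi (variance = mu + phi * mu^2),
#' \deqn{\hat\phi_g^{raw} = \frac{\sum_k SS_k - \sum_k (n_k-1)\bar{x}_k}
#'   {\sum_k (n_k-1) \bar{x}_k^2},}
#' floored at 0, then shrunk toward the across-gene mean dispersion with
#' weight `w`: `phi_hat = (1 - w) * phi_raw + w * phi_common`. The shrinkage
#' stabilizes the very noisy per-gene moments at small replicate numbers.
#'
#' @param cm A normalized `count_matrix` (or a raw one plus `sf`).
#' @param groups Character/factor vector of group labels, one per sample.
#' @param w Shrinkage weight toward the common dispersion, default 0.7 (a
#'   precision-based choice: the per-gene moments carry only a few residual
#'   degrees of freedom at typical replicate numbers, so most weight goes to
#'   the stable across-gene value, as moderated-dispersion methods do).
#' @return Named numeric vector of per-gene dispersions `phi_hat >= 0`, with
#'   the common dispersion in attribute `common`.
#' @export
estimate_dispersion <- function(cm, groups, w = 0.7) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- normalized_values(cm)
  if (length(groups) != ncol(m))
    abort_validation("groups must have one label per sample")
  tab <- table(groups)
  if (all(tab < 2))
    abort_validation("dispersion needs >= 2 replicates in some group")
  ss <- 0; s1 <- 0; s2 <- 0
  for (g in names(tab)) {
    sub <- m[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
    s1 <- s1 + (ncol(sub) - 1) * mu
    s2 <- s2 + (ncol(sub) - 1) * mu^2
  }
  raw <- ifelse(s2 > 0, pmax(0, (ss - s1) / s2), 0)
  common <- mean(raw)
  stats::setNames(structure((1 - w) * raw + w * common, common = common),
                  rownames(m))
}

## CPM-scale values if raw, pass-through if already normalized by the caller.
normalized_values <- function(cm, sf = NULL) {
  if (cm$normalized) return(cm$counts)
  if (is.null(sf)) sf <- size_factors(cm)
  sweep(cm$counts, 2, sf, `/`)
}

#' Two-group negative-binomial likelihood-ratio test
#'
#' In-house differential expression for a two-group design. Per gene, raw
#' counts \eqn{y_{ij}} are modeled as NB with mean \eqn{s_j q_i} (size
#' factors \eqn{s_j}) and fixed dispersion \eqn{\hat\phi_i}; the
#' maximum-likelihood abundance \eqn{q} is fit under equal means (null) and
#' free per-group means (alternative) by Newton iteration on the score
#' equation \eqn{\sum_j (y_j - s_j q)/(1 + \phi s_j q) = 0}, and the
#' likelihood ratio is referred to chi-square with 1 df. The reported log2
#' fold change is computed from normalized group means with pseudocount 0.5;
#' p-values are Benjamini-Hochberg adjusted over all tested genes.
#'
#' Genes with all-zero counts are dropped before testing (reported via a
#' message).
#'
#' @param cm A raw `count_matrix`.
#' @param groups Vector of exactly two distinct group labels, one per
#'   sample; the fold change is the second level (B) versus the first (A),
#'   with levels taken from the factor levels or, for character input, in
#'   sorted order (so relabeling samples negates every fold change).
#' @param dispersion Optional per-gene dispersions; estimated with
#'   [estimate_dispersion()] when `NULL`.
#' @param sf Optional size factors; computed with [size_factors()] when
#'   `NULL`.
#' @param pseudocount Pseudocount on normalized group means for the fold
#'   change, default 0.5.
#' @return A data.frame of class `de_result` with columns `gene`,
#'   `base_mean`, `log2fc`, `pvalue`, `padj`.
#' @export
nb_test <- function(cm, groups, dispersion = NULL, sf = NULL,
                    pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$normalized)
    abort_validation("nb_test needs raw counts (it normalizes internally)")
  lev <- if (is.factor(groups)) levels(droplevels(groups))
         else sort(unique(as.character(groups)))
  groups <- as.character(groups)
  if (length(groups) != ncol(cm$counts))
    abort_validation("groups must have one label per sample")
  if (length(lev) != 2)
    abort_validation("nb_test needs exactly two groups")
  if (any(table(groups) < 1))
    abort_validation("each group needs at least one sample")
  keep <- rowSums(cm$counts) > 0
  if (!all(keep))
    message(sprintf("dropping %d gene(s) with all-zero counts", sum(!keep)))
  y <- cm$counts[keep, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(y, 2, sf, `/`)
  if (is.null(dispersion)) {
    cmn <- count_matrix(norm, samples = cm$samples, normalized = TRUE)
    dispersion <- estimate_dispersion(cmn, groups)
  } else {
    dispersion <- dispersion[rownames(y)]
  }
  phi <- pmax(as.numeric(dispersion), 0)

  a <- groups == lev[1]
  b <- groups == lev[2]
  ll0 <- nb_profile_loglik(y, sf, phi)
  lla <- nb_profile_loglik(y[, a, drop = FALSE], sf[a], phi)
  llb <- nb_profile_loglik(y[, b, drop = FALSE], sf[b], phi)
  lrt <- pmax(0, 2 * (lla + llb - ll0))
  pvalue <- pmin(1, stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  pvalue <- pmax(pvalue, .Machine$double.xmin)

  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  out <- data.frame(gene = rownames(y),
                    base_mean = rowMeans(norm),
                    log2fc = log2((mean_b + pseudocount) /
                                  (mean_a + pseudocount)),
                    pvalue = pvalue,
                    padj = bh_adjust(pvalue),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- lev
  class(out) <- c("de_result", "data.frame")
  out
}

## Profile NB log-likelihood at the MLE of a common abundance q (mu_j = s_j q)
## with fixed per-gene dispersion phi. Vectorized Newton on the score
## U(q) = sum_j (y_j - s_j q) / (1 + phi s_j q), which is monotone in q.
nb_profile_loglik <- function(y, s, phi) {
  n_gene <- nrow(y)
  q <- rowSums(y) / sum(s)
  active <- q > 0
  for (it in seq_len(100)) {
    if (!any(active)) break
    qa <- q[active]
    pa <- phi[active]
    ya <- y[active, , drop = FALSE]
    den <- 1 + outer(pa * qa, s)
    u <- rowSums((ya - outer(qa, s)) / den)
    du <- -rowSums(sweep((1 + sweep(ya, 1, pa, `*`)) / den^2, 2, s, `*`))
    step <- u / du
    qn <- pmax(qa - step, qa / 10)
    conv <- abs(qn - qa) <= 1e-10 * (qa + 1e-10)
    q[active] <- qn
    active[active] <- !conv
  }
  mu <- outer(q, s)
  size <- 1 / pmax(phi, 1e-12)
  ll <- stats::dnbinom(y, mu = mu, size = matrix(size, n_gene, ncol(y)),
                       log = TRUE)
  rowSums(ll)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control, with monotonicity enforcement and
#' clipping at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    abort_validation("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance filter for differential expression
#'
#' Partition into up- and down-regulated gene sets using a strict p-value
#' cutoff (`p < p_max`; the boundary p = p_max is excluded) and an inclusive
#' minimum absolute log2 fold change (`|lfc| >= min_abs_lfc`). Defaults
#' p_max = 0.05, min_abs_lfc = 0.58 (about 1.5-fold). The unadjusted p-value
#' is used by default, with `use_fdr = TRUE` switching to `padj`.
#'
#' @param results A `de_result` table.
#' @param p_max Strict upper bound on the p-value.
#' @param min_abs_lfc Inclusive minimum |log2 fold change|.
#' @param use_fdr Filter on `padj` instead of `pvalue`.
#' @return A list of character vectors `up` and `down`.
#' @export
filter_de <- function(results, p_max = 0.05, min_abs_lfc = 0.58,
                      use_fdr = FALSE) {
  if (!nrow(results)) abort_validation("results must be non-empty")
  p <- if (use_fdr) results$padj else results$pvalue
  sig <- p < p_max
  list(up = results$gene[sig & results$log2fc >= min_abs_lfc],
       down = results$gene[sig & results$log2fc <= -min_abs_lfc])
}
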