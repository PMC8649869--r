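#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT (set name, description, member genes...).
#' Parsing delegates to [fgsea::gmtPathways()]; set names must be unique and
#' sets non-empty.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene symbols, case-normalized).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("GMT file not found: %s", path))
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    abort_validation("gene-set names must be unique")
  if (any(lengths(sets) == 0))
    abort_validation("gene sets must be non-empty")
  lapply(sets, normalize_symbols)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least `k = |query ∩ set|` members
#' of `set` in `|query|` draws without replacement from `universe`
#' (equivalent to a one-sided Fisher exact test on the 2x2 table).
#'
#' @param query,set,universe Character vectors; `query` and `set` must be
#'   subsets of `universe`.
#' @return A list: `p` (P[X >= k]), `k`, `m` (set size), `n` (query size),
#'   `N` (universe size).
#' @export
hypergeom_test <- function(query, set, universe) {
  query <- normalize_symbols(query)
  set <- normalize_symbols(set)
  universe <- normalize_symbols(universe)
  out_q <- setdiff(query, universe)
  out_s <- setdiff(set, universe)
  if (length(out_q) || length(out_s))
    abort_validation(sprintf(
      "genes outside the universe: %s",
      paste(utils::head(c(out_q, out_s), 10), collapse = ", ")))
  k <- length(intersect(query, set))
  m <- length(set)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  list(p = min(1, p), k = k, m = m, n = n, N = N)
}

#' Over-representation analysis of a query set against a collection
#'
#' Applies [hypergeom_test()] to every set of a collection and adjusts with
#' Benjamini-Hochberg. Sets are intersected with the universe first (the
#' background of an ORA is the measured universe, not the genome).
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Background gene universe.
#' @param p_cutoff Inclusive significance threshold on the unadjusted p
#'   (default 0.05); rows are flagged, not removed.
#' @return data.frame with columns `set_name`, `overlap_k`, `set_size_m`,
#'   `query_size_n`, `universe_N`, `p_hyper`, `padj`, `significant`.
#' @export
enrich_ora <- function(query, collection, universe, p_cutoff = 0.05) {
  universe <- normalize_symbols(universe)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(normalize_symbols(collection[[nm]]), universe)
    h <- hypergeom_test(query, s, universe)
    data.frame(set_name = nm, overlap_k = h$k, set_size_m = h$m,
               query_size_n = h$n, universe_N = h$N, p_hyper = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_hyper)
  out$significant <- out$p_hyper <= p_cutoff
  out[order(out$p_hyper), , drop = FALSE]
}

#' GSEA-style weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic on an ordered gene list:
#' walking down the ranking, the running sum gains
#' \eqn{|r_i|^p / \sum_{hits} |r|^p} at set members and loses
#' \eqn{1/(N - m)} at non-members; the enrichment score is the running sum's
#' signed extremum, always in `[-1, 1]`.
#'
#' @param ranked Named numeric vector of scores, already ordered by the
#'   caller (typically decreasing); names are gene symbols.
#' @param set Character vector of member genes; must overlap the ranking
#'   and must not cover all of it.
#' @param p Weight exponent on |score| (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return A list: `es` and the full `running` profile (length `N`).
#' @export
gsea_es <- function(ranked, set, p = 1) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    abort_validation("ranked must be a named vector with unique gene names")
  genes <- toupper(trimws(names(ranked)))
  set <- normalize_symbols(set)
  hit <- genes %in% set
  N <- length(ranked)
  m <- sum(hit)
  if (m == 0) abort_validation("gene set is disjoint from the ranked list")
  if (m == N) abort_validation("gene set covers the entire ranked list")
  w <- abs(ranked)^p
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / m
  dec <- (!hit) / (N - m)
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(es = unname(es), running = unname(running))
}

#' Gene-permutation p-value for the enrichment score
#'
#' Null distribution from random reassignment of set membership over the
#' ranked list (gene permutation; the pipeline consumes a single ranked
#' list, so phenotype permutation is unavailable). Uses the add-one
#' estimator `p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)`.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A list: `es`, `p_perm`, `n_perm`.
#' @export
gsea_perm_p <- function(ranked, set, n_perm = 1000L, seed = 1L, p = 1) {
  if (!is_count(n_perm) || n_perm < 100)
    abort_parameter("n_perm must be an integer >= 100")
  obs <- gsea_es(ranked, set, p = p)
  genes <- toupper(trimws(names(ranked)))
  m <- sum(genes %in% normalize_symbols(set))
  N <- length(ranked)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, m)
    fake <- genes[idx]
    gsea_es(ranked, fake, p = p)$es
  }, numeric(1)))
  pval <- (1 + sum(abs(perm_es) >= abs(obs$es))) / (1 + n_perm)
  list(es = obs$es, p_perm = pval, n_perm = n_perm)
}
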