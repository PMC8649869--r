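## Independent brute-force oracles and tiny fixture builders. These are kept
## deliberately naive (loops, enumeration) and share no code with the
## implementation paths they check.

tiny_library <- function(n_genes = 3, shrnas_per_gene = 2, barcodes = NULL) {
  n <- n_genes * shrnas_per_gene
  if (is.null(barcodes)) {
    ## deterministic, maximally separated 8-mers
    pool <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                  paste, collapse = "")
    barcodes <- paste0(pool[seq_len(n)], strrep("A", 4))
  }
  as_shrna_library(data.frame(
    shrna_id = sprintf("sh%02d", seq_len(n)),
    gene = rep(sprintf("g%02d", seq_len(n_genes)), each = shrnas_per_gene),
    barcode = barcodes, stringsAsFactors = FALSE))
}

## Plain-text FASTQ writer independent of the package's emitter.
write_raw_fastq <- function(seqs, path) {
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  rec <- as.vector(rbind(sprintf("@read%d", seq_along(seqs)), seqs, "+",
                         vapply(seqs, function(s) strrep("I", nchar(s)), "")))
  writeLines(rec, path)
  invisible(path)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Sliding-window anchor locator: try every start position, allow <= 1
## mismatching character in the flank, return the following k bases.
oracle_anchor_extract <- function(read, flank, k) {
  n <- nchar(read)
  fl <- nchar(flank)
  for (p in seq_len(max(0, n - fl - k + 1))) {
    if (oracle_hamming(substr(read, p, p + fl - 1), flank) <= 1)
      return(substr(read, p + fl, p + fl + k - 1))
  }
  NA_character_
}

## Exhaustive nearest-barcode assignment by full Hamming scan.
oracle_assign <- function(bc, barcodes, max_mismatch) {
  d <- vapply(barcodes, function(b) oracle_hamming(bc, b), numeric(1))
  best <- min(d)
  if (best > max_mismatch || sum(d == best) > 1) return(NA_integer_)
  which.min(d)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

oracle_median_of_ratios <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) median(col / ref))
  sf / exp(mean(log(sf)))
}

## Step-by-step GSEA running sum with an explicit loop.
oracle_gsea <- function(scores, hit, p) {
  N <- length(scores)
  m <- sum(hit)
  nr <- sum(abs(scores[hit])^p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(scores[i])^p / nr else cur - 1 / (N - m)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

## Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_tail <- function(k, m, n, N) {
  if (k <= 0) return(1)
  j <- k:min(m, n)
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

## Region counts by explicit membership enumeration.
oracle_venn <- function(sets) {
  u <- unique(toupper(trimws(unlist(sets))))
  k <- length(sets)
  out <- integer(0)
  labs <- character(0)
  pat <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  for (r in seq_len(nrow(pat))) {
    inside <- rep(TRUE, length(u))
    for (j in seq_len(k)) {
      member <- u %in% toupper(trimws(sets[[j]]))
      inside <- inside & (if (pat[r, j]) member else !member)
    }
    out <- c(out, sum(inside))
    labs <- c(labs, paste(names(sets)[unlist(pat[r, ])], collapse = "&"))
  }
  setNames(out, labs)
}

## Poisson two-group LRT, closed form MLEs.
oracle_poisson_lrt <- function(y, s, grp) {
  ll <- function(y, s) {
    q <- sum(y) / sum(s)
    if (q == 0) return(0)
    sum(dpois(y, s * q, log = TRUE))
  }
  a <- grp == unique(grp)[1]
  2 * (ll(y[a], s[a]) + ll(y[!a], s[!a]) - ll(y, s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
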