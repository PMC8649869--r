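#' Barcode matching policy
#'
#' Controls how the barcode segment is located in a read and how it is
#' assigned to the library. Two extraction modes are provided because vector
#' layouts differ between kits: a fixed 0-based `offset`, or an anchored mode
#' that locates the 5' flank (allowing at most one substitution) and takes
#' the following `barcode_length` bases. Assignment tolerates `max_mismatch`
#' Hamming mismatches on the barcode itself; an extracted barcode at equal
#' admissible distance to two library barcodes is never counted. Matching is
#' case-insensitive and `N` never matches.
#'
#' @param max_mismatch 0 or 1 barcode mismatches tolerated.
#' @param mode `"anchored"` or `"offset"`.
#' @param offset 0-based start of the barcode (offset mode).
#' @param flank5 5' anchor sequence (anchored mode).
#' @return A `match_policy` object.
#' @export
match_policy <- function(max_mismatch = 1L, mode = c("anchored", "offset"),
                         offset = 0L, flank5 = NULL) {
  mode <- match.arg(mode)
  if (!max_mismatch %in% c(0L, 1L))
    abort_parameter("max_mismatch must be 0 or 1")
  if (mode == "anchored" && (is.null(flank5) || !nzchar(flank5)))
    abort_parameter("anchored mode requires a non-empty flank5")
  if (mode == "offset" && (!is_count(offset) || offset < 0))
    abort_parameter("offset must be a non-negative integer")
  structure(list(max_mismatch = as.integer(max_mismatch), mode = mode,
                 offset = as.integer(offset),
                 flank5 = if (is.null(flank5)) NULL else toupper(flank5)),
            class = "match_policy")
}

#' Extract the barcode segment from reads
#'
#' Vectorized over reads. Offset mode takes the fixed substring; anchored
#' mode locates `flank5` (leftmost position, at most one substitution) and
#' returns the `barcode_length` bases that follow. Reads too short, or with
#' no admissible anchor, give `NA` (a no-call, tallied as a discard by
#' [count_barcodes()], never an error).
#'
#' @param reads Character vector of read sequences.
#' @param policy A `match_policy`.
#' @param barcode_length Barcode length in nucleotides.
#' @return Character vector of barcodes, `NA` for no-calls.
#' @export
extract_barcode <- function(reads, policy, barcode_length) {
  stopifnot(inherits(policy, "match_policy"))
  reads <- toupper(reads)
  n <- nchar(reads)
  if (policy$mode == "offset") {
    out <- substr(reads, policy$offset + 1L, policy$offset + barcode_length)
    out[n < policy$offset + barcode_length] <- NA_character_
    return(out)
  }
  fl <- policy$flank5
  fl_len <- nchar(fl)
  out <- rep(NA_character_, length(reads))
  ## fast path: anchor sits exactly at the read start
  at_start <- n >= fl_len + barcode_length &
    substr(reads, 1L, fl_len) == fl
  out[at_start] <- substr(reads[at_start], fl_len + 1L,
                          fl_len + barcode_length)
  todo <- which(!at_start & n >= fl_len + barcode_length)
  if (length(todo)) {
    fl_int <- utf8ToInt(fl)
    for (i in todo) {
      r_int <- utf8ToInt(reads[i])
      last <- n[i] - fl_len - barcode_length + 1L
      for (p in seq_len(last)) {
        if (sum(r_int[p:(p + fl_len - 1L)] != fl_int) <= 1L) {
          out[i] <- substr(reads[i], p + fl_len,
                           p + fl_len + barcode_length - 1L)
          break
        }
      }
    }
  }
  out
}

## One-mismatch lookup table: every Hamming-1 neighbor of every library
## barcode, mapped to its row index. Neighbors that are themselves library
## barcodes are dropped (exact match takes precedence at distance 0);
## neighbors shared by two barcodes are kept with index NA so that ambiguous
## reads are discarded, never double counted.
build_mm1_index <- function(barcodes) {
  len <- nchar(barcodes[1])
  keys <- character(0)
  vals <- integer(0)
  for (j in seq_len(len)) {
    orig <- substr(barcodes, j, j)
    for (b in c("A", "C", "G", "T")) {
      keep <- orig != b
      v <- barcodes[keep]
      substr(v, j, j) <- b
      keys <- c(keys, v)
      vals <- c(vals, which(keep))
    }
  }
  inside <- keys %in% barcodes
  keys <- keys[!inside]
  vals <- vals[!inside]
  ord <- order(keys)
  keys <- keys[ord]
  vals <- vals[ord]
  dup_grp <- keys[duplicated(keys)]
  vals[keys %in% dup_grp] <- NA_integer_
  first <- !duplicated(keys)
  list(keys = keys[first], vals = vals[first])
}

#' Count barcode reads per sample against a library
#'
#' Every read contributes to exactly one count cell or to the per-sample
#' discard tally (no-call, unmatched, or ambiguous), so
#' `colSums(counts) + discards` conserves the read totals.
#'
#' @param fastq_paths Character vector of per-sample FASTQ paths (plain or
#'   gzip). Names, when present, become sample ids; otherwise the file base
#'   name is used.
#' @param lib A `shrna_library`.
#' @param policy A `match_policy`; defaults to anchored mode with the
#'   default flank of [write_barcode_fastq()] and one tolerated mismatch.
#' @return A list: `counts` (a raw `count_matrix`, shRNAs x samples, with
#'   the library's gene map) and `discards` (named integer per sample).
#' @export
count_barcodes <- function(fastq_paths, lib,
                           policy = match_policy(flank5 = "ACGGTAGC")) {
  stopifnot(inherits(lib, "shrna_library"), inherits(policy, "match_policy"))
  ids <- names(fastq_paths)
  if (is.null(ids)) ids <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                               basename(fastq_paths))
  if (anyDuplicated(ids)) abort_validation("sample names must be unique")
  bl <- barcode_length(lib)
  mm1 <- if (policy$max_mismatch >= 1L) build_mm1_index(lib$barcode) else NULL
  m <- matrix(0L, nrow = nrow(lib), ncol = length(fastq_paths),
              dimnames = list(lib$shrna_id, ids))
  discards <- stats::setNames(integer(length(fastq_paths)), ids)
  for (j in seq_along(fastq_paths)) {
    seqs <- read_fastq_seqs(fastq_paths[j])
    bcs <- extract_barcode(seqs, policy, bl)
    idx <- match(bcs, lib$barcode)
    if (!is.null(mm1)) {
      una <- which(is.na(idx) & !is.na(bcs))
      if (length(una)) {
        pos <- match(bcs[una], mm1$keys)
        idx[una] <- ifelse(is.na(pos), NA_integer_, mm1$vals[pos])
      }
    }
    hit <- !is.na(idx)
    m[, j] <- tabulate(idx[hit], nbins = nrow(lib))
    discards[j] <- length(seqs) - sum(hit)
  }
  cm <- count_matrix(m,
                     features = data.frame(feature_id = lib$shrna_id,
                                           gene = lib$gene,
                                           stringsAsFactors = FALSE))
  list(counts = cm, discards = discards)
}
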