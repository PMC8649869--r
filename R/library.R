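#' Generate a barcoded shRNA library
#'
#' Draws a synthetic pooled shRNA library: `n_genes` gene symbols, each
#' covered by `shrnas_per_gene` hairpins, every hairpin carrying a unique
#' fixed-length nucleotide barcode. Real genome-scale pools are of the order
#' of 6,000 genes and 50,000 hairpins with at least eight hairpins per gene;
#' the generator reproduces that structure at any requested scale.
#'
#' @param n_genes Number of genes (>= 1).
#' @param shrnas_per_gene Hairpins per gene (>= 1; screens typically use >= 8
#'   so that multi-hairpin gene filters are meaningful).
#' @param barcode_length Barcode length in nucleotides; `4^barcode_length`
#'   must be at least the library size.
#' @param seed Integer seed; the library is a pure function of its arguments.
#' @return A `shrna_library`: a data.frame with columns `shrna_id`, `gene`,
#'   `barcode` and a `barcode_length` attribute. Barcodes are pairwise
#'   distinct.
#' @export
generate_library <- function(n_genes, shrnas_per_gene = 8L,
                             barcode_length = 18L, seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1)
    abort_parameter("n_genes must be a positive integer")
  if (!is_count(shrnas_per_gene) || shrnas_per_gene < 1)
    abort_parameter("shrnas_per_gene must be a positive integer")
  if (!is_count(barcode_length) || barcode_length < 1)
    abort_parameter("barcode_length must be a positive integer")
  n <- n_genes * shrnas_per_gene
  if (4^barcode_length < n)
    abort_parameter(sprintf(
      "barcode space too small: need %d barcodes, 4^%d = %.0f available",
      n, barcode_length, 4^barcode_length))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  shrna_id <- sprintf("%s_sh%02d", rep(genes, each = shrnas_per_gene),
                      rep(seq_len(shrnas_per_gene), times = n_genes))
  barcodes <- with_seed(seed, draw_unique_barcodes(n, barcode_length))
  lib <- data.frame(shrna_id = shrna_id,
                    gene = rep(genes, each = shrnas_per_gene),
                    barcode = barcodes,
                    stringsAsFactors = FALSE)
  as_shrna_library(lib)
}

## Rejection-sample distinct barcodes; the precondition guarantees success.
draw_unique_barcodes <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    m <- matrix(sample(bases, k * len, replace = TRUE), nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  out <- unique(draw(n))
  while (length(out) < n) {
    out <- unique(c(out, draw(n - length(out) + 8L)))
  }
  out[seq_len(n)]
}

#' Validate and classify a shRNA library table
#'
#' @param lib A data.frame with columns `shrna_id`, `gene`, `barcode`.
#' @return The validated table with class `shrna_library` and a
#'   `barcode_length` attribute.
#' @export
as_shrna_library <- function(lib) {
  need <- c("shrna_id", "gene", "barcode")
  if (!all(need %in% names(lib)))
    abort_validation("library table needs columns shrna_id, gene, barcode")
  if (anyDuplicated(lib$shrna_id))
    abort_validation("shrna_id values must be unique")
  if (anyDuplicated(lib$barcode))
    abort_validation("barcodes must be unique library-wide")
  if (any(!nzchar(lib$gene)) || anyNA(lib$gene))
    abort_validation("every record needs a non-empty gene symbol")
  lens <- unique(nchar(lib$barcode))
  if (length(lens) != 1)
    abort_validation("barcode length must be uniform across the library")
  if (any(grepl("[^ACGT]", lib$barcode)))
    abort_validation("barcodes must be over the alphabet {A,C,G,T}")
  structure(as.data.frame(lib[, need], stringsAsFactors = FALSE),
            barcode_length = lens,
            class = c("shrna_library", "data.frame"))
}

#' @rdname as_shrna_library
#' @param x Object to query.
#' @export
barcode_length <- function(x) attr(x, "barcode_length")

#' Read / write a shRNA library TSV
#'
#' The interchange format is a TSV with header columns `shrna_id`, `gene`,
#' `barcode`.
#'
#' @param lib A `shrna_library`.
#' @param path File path.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "shrna_library"))
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  as_shrna_library(utils::read.delim(path, stringsAsFactors = FALSE))
}
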