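#' Emit barcode reads as FASTQ
#'
#' Inverts the counting step for testing and demonstration: every count cell
#' becomes exactly that many reads of the form `flank5 + barcode + flank3`,
#' with independent per-base substitution errors at `error_rate`. Qualities
#' are constant Sanger/Phred+33 "I"; one FASTQ file is written per sample.
#'
#' @param cm A raw `count_matrix` whose features are library shRNA ids (or
#'   barcodes).
#' @param lib The `shrna_library` the rows refer to.
#' @param out_dir Output directory; files are named `<sample>.fastq` (plus
#'   `.gz` when `compress = TRUE`).
#' @param flank5,flank3 Constant vector sequence flanking the barcode.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed.
#' @param compress Write gzip-compressed FASTQ.
#' @return Named integer vector: reads written per sample, with the file
#'   paths in attribute `paths`.
#' @export
write_barcode_fastq <- function(cm, lib, out_dir,
                                flank5 = "ACGGTAGC", flank3 = "GTCCTAAG",
                                error_rate = 0, seed = 1L, compress = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "shrna_library"))
  if (cm$normalized)
    abort_validation("write_barcode_fastq needs raw integer counts")
  if (error_rate < 0 || error_rate >= 0.25)
    abort_parameter("error_rate must lie in [0, 0.25)")
  miss <- setdiff(rownames(cm$counts), lib$shrna_id)
  if (length(miss))
    abort_validation(sprintf("count rows not in library: %s",
                             paste(utils::head(miss, 5), collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bc <- lib$barcode[match(rownames(cm$counts), lib$shrna_id)]
  template <- paste0(flank5, bc, flank3)
  read_len <- nchar(template[1])
  totals <- integer(ncol(cm$counts))
  names(totals) <- colnames(cm$counts)
  paths <- character(ncol(cm$counts))
  with_seed(seed, {
    for (j in seq_along(totals)) {
      n <- cm$counts[, j]
      reads <- rep(template, times = n)
      if (error_rate > 0 && length(reads))
        reads <- mutate_reads(reads, read_len, error_rate)
      sample_id <- colnames(cm$counts)[j]
      fp <- file.path(out_dir, paste0(sample_id, ".fastq",
                                      if (compress) ".gz" else ""))
      dna <- Biostrings::DNAStringSet(reads)
      if (length(dna))
        names(dna) <- sprintf("%s.%d", sample_id, seq_along(dna))
      qual <- Biostrings::BStringSet(rep(strrep("I", read_len), length(dna)))
      Biostrings::writeXStringSet(dna, fp, format = "fastq",
                                  qualities = qual, compress = compress)
      totals[j] <- length(reads)
      paths[j] <- fp
    }
  })
  names(paths) <- names(totals)
  structure(totals, paths = paths)
}

## Independent per-base substitutions; each error picks one of the 3 other
## bases uniformly.
mutate_reads <- function(reads, read_len, error_rate) {
  n_base <- length(reads) * read_len
  hits <- which(stats::runif(n_base) < error_rate)
  if (!length(hits)) return(reads)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (h in hits) {
    i <- (h - 1L) %/% read_len + 1L
    j <- (h - 1L) %% read_len + 1L
    cur <- substr(reads[i], j, j)
    substr(reads[i], j, j) <- sample(alt[[cur]], 1L)
  }
  reads
}

## Reads a FASTQ (plain or gzip) into a character vector of sequences,
## wrapping parser failures with the offending file name.
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("FASTQ file not found: %s", path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(character(0))
  dna <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e)
                    abort_io(sprintf("malformed FASTQ %s: %s", path,
                                     conditionMessage(e))))
  as.character(dna)
}
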