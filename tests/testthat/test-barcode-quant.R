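test_that("barcode extraction handles offset, anchored and degenerate reads", {
  pol_anchor <- match_policy(flank5 = "ACGTAC")
  expect_equal(extract_barcode("ACGTACGGGGCCCCTTTT", pol_anchor, 8),
               "GGGGCCCC")
  pol_off <- match_policy(mode = "offset", offset = 0)
  expect_equal(extract_barcode("ACGTACGTTT", pol_off, 8), "ACGTACGT")
  ## too short for the requested segment: no-call, not an error
  expect_true(is.na(extract_barcode("ACGT", pol_off, 8)))
  expect_true(is.na(extract_barcode("ACGTACGG", pol_anchor, 8)))
  ## one substitution inside the anchor is tolerated
  expect_equal(extract_barcode("ACCTACGGGGCCCCTTTT", pol_anchor, 8),
               "GGGGCCCC")
})

test_that("anchored extraction equals the sliding-window oracle on random reads", {
  set.seed(41)
  flank <- "ACGGTAGC"
  pol <- match_policy(flank5 = flank)
  for (i in 1:60) {
    pad5 <- paste(sample(c("A", "C", "G", "T"), sample(0:5, 1), TRUE),
                  collapse = "")
    bc <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    read <- paste0(pad5, flank, bc, "GTTA")
    ## sometimes corrupt one anchor base
    if (i %% 3 == 0) {
      p <- nchar(pad5) + sample(8, 1)
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
    expect_identical(extract_barcode(read, pol, 10),
                     oracle_anchor_extract(read, flank, 10))
  }
})

test_that("counting tallies reads exactly and conserves totals", {
  lib <- tiny_library(3, 1, barcodes = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"))
  dir <- withr::local_tempdir()
  reads <- c(rep(paste0("TTGG", "AAAAAAAA"), 5),
             rep(paste0("TTGG", "CCCCCCCC"), 2),
             paste0("TTGG", "TTTTTTTT"))   # junk, distance > 1 to all
  write_raw_fastq(reads, file.path(dir, "s1.fastq"))
  pol <- match_policy(max_mismatch = 0, mode = "offset", offset = 4)
  res <- count_barcodes(c(s1 = file.path(dir, "s1.fastq")), lib, pol)
  expect_equal(unname(res$counts$counts[, "s1"]), c(5, 2, 0))
  expect_equal(unname(res$discards["s1"]), 1)
  expect_equal(sum(res$counts$counts) + sum(res$discards), length(reads))
})

test_that("empty FASTQ gives an all-zero column with no discards", {
  lib <- tiny_library(2, 1)
  dir <- withr::local_tempdir()
  write_raw_fastq(character(0), file.path(dir, "empty.fastq"))
  res <- count_barcodes(c(e = file.path(dir, "empty.fastq")), lib,
                        match_policy(max_mismatch = 0, mode = "offset"))
  expect_equal(unname(res$counts$counts[, "e"]), c(0, 0))
  expect_equal(unname(res$discards["e"]), 0)
})

test_that("mismatch-1 assignment equals an exhaustive Hamming scan", {
  set.seed(17)
  lib <- generate_library(10, 2, 10, seed = 31)
  for (mm in c(0L, 1L)) {
    bcs <- character(0)
    for (i in 1:80) {
      bc <- lib$barcode[sample(nrow(lib), 1)]
      nerr <- sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
      pos <- sample(10, nerr)
      for (p in pos)
        substr(bc, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(bc, p, p)), 1)
      bcs <- c(bcs, bc)
    }
    dir <- withr::local_tempdir()
    write_raw_fastq(bcs, file.path(dir, "x.fastq"))
    pol <- match_policy(max_mismatch = mm, mode = "offset", offset = 0)
    res <- count_barcodes(c(x = file.path(dir, "x.fastq")), lib, pol)
    want <- integer(nrow(lib))
    for (bc in bcs) {
      j <- oracle_assign(bc, lib$barcode, mm)
      if (!is.na(j)) want[j] <- want[j] + 1L
    }
    expect_equal(unname(res$counts$counts[, "x"]), want)
    expect_equal(unname(res$discards["x"]),
                 length(bcs) - sum(want))
  }
})

test_that("ambiguous reads equidistant to two barcodes are discarded", {
  lib <- tiny_library(2, 1, barcodes = c("AAAAAAAA", "AAAAAATT"))
  dir <- withr::local_tempdir()
  ## distance 1 to both library barcodes
  write_raw_fastq("AAAAAAAT", file.path(dir, "a.fastq"))
  res <- count_barcodes(c(a = file.path(dir, "a.fastq")), lib,
                        match_policy(max_mismatch = 1, mode = "offset"))
  expect_equal(sum(res$counts$counts), 0)
  expect_equal(unname(res$discards["a"]), 1)
})

test_that("count matrices are invariant to read order", {
  lib <- generate_library(6, 2, 9, seed = 13)
  set.seed(5)
  reads <- rep(lib$barcode, times = rpois(nrow(lib), 4))
  dir <- withr::local_tempdir()
  write_raw_fastq(reads, file.path(dir, "o1.fastq"))
  write_raw_fastq(sample(reads), file.path(dir, "o2.fastq"))
  pol <- match_policy(max_mismatch = 1, mode = "offset")
  r1 <- count_barcodes(c(s = file.path(dir, "o1.fastq")), lib, pol)
  r2 <- count_barcodes(c(s = file.path(dir, "o2.fastq")), lib, pol)
  expect_identical(r1$counts$counts, r2$counts$counts)
})

test_that("FASTQ emission inverts exactly at zero error rate", {
  lib <- generate_library(8, 3, 12, seed = 21)
  set.seed(9)
  m <- matrix(rpois(24 * 2, 20), 24, 2,
              dimnames = list(lib$shrna_id, c("s1", "s2")))
  cm <- count_matrix(m)
  dir <- withr::local_tempdir()
  totals <- write_barcode_fastq(cm, lib, dir, error_rate = 0, seed = 2)
  expect_equal(as.vector(totals), unname(colSums(m)))
  res <- count_barcodes(attr(totals, "paths"), lib,
                        match_policy(max_mismatch = 0, flank5 = "ACGGTAGC"))
  expect_equal(res$counts$counts[rownames(m), colnames(m)], m)
  expect_equal(sum(res$discards), 0)
  ## exact per-barcode emission: 3 reads of bc1, none of bc2
  m2 <- matrix(c(3L, 0L), 2, 1,
               dimnames = list(lib$shrna_id[1:2], "only"))
  lib2 <- as_shrna_library(lib[1:2, ])
  t2 <- write_barcode_fastq(count_matrix(m2), lib2, dir, error_rate = 0,
                            seed = 1)
  lines <- readLines(file.path(dir, "only.fastq"))
  expect_equal(length(lines), 12)  # 3 reads x 4 lines
  expect_true(all(substr(lines[c(2, 6, 10)], 9, 20) == lib2$barcode[1]))
})

test_that("unknown count rows and malformed FASTQ are rejected with context", {
  lib <- tiny_library(2, 1)
  m <- matrix(1L, 1, 1, dimnames = list("nonexistent", "s"))
  expect_error(write_barcode_fastq(count_matrix(m), lib, tempdir()),
               "not in library")
  dir <- withr::local_tempdir()
  writeLines(c("garbage line", "ACGT"), file.path(dir, "bad.fastq"))
  expect_error(count_barcodes(c(b = file.path(dir, "bad.fastq")), tiny_library(2, 1),
                              match_policy(max_mismatch = 0, mode = "offset")),
               "bad.fastq")
})

test_that("CPM normalization matches closed form and brute-force scaling", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  out <- cpm_normalize(count_matrix(m))
  expect_equal(unname(out$counts[, 1]), c(250000, 250000, 500000))
  expect_true(out$normalized)
  set.seed(3)
  m2 <- matrix(rpois(300, 40), 50, 6,
               dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:6)))
  norm <- cpm_normalize(count_matrix(m2))$counts
  expect_equal(unname(colSums(norm)), rep(1e6, 6), tolerance = 1e-6)
  brute <- apply(m2, 2, function(col) col / sum(col) * 1e6)
  expect_equal(unname(norm), unname(brute))
  m2[, 3] <- 0
  expect_error(cpm_normalize(count_matrix(m2)), "s3")
})
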