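test_that("generated libraries have the requested shape and unique barcodes", {
  lib <- generate_library(3, 8, 18, seed = 1)
  expect_s3_class(lib, "shrna_library")
  expect_equal(nrow(lib), 24)
  expect_equal(length(unique(lib$gene)), 3)
  expect_true(all(table(lib$gene) == 8))
  expect_false(anyDuplicated(lib$barcode) > 0)
  expect_equal(barcode_length(lib), 18)
  expect_true(all(grepl("^[ACGT]{18}$", lib$barcode)))
})

test_that("library generation is deterministic and respects the barcode space", {
  expect_identical(generate_library(5, 4, 10, seed = 7),
                   generate_library(5, 4, 10, seed = 7))
  expect_false(identical(generate_library(5, 4, 10, seed = 7),
                         generate_library(5, 4, 10, seed = 8)))
  ## 4 barcodes needed, 4^1 available: boundary is allowed
  expect_silent(lib <- generate_library(2, 2, 1, seed = 1))
  expect_equal(sort(lib$barcode), c("A", "C", "G", "T"))
  ## 5 barcodes cannot fit in 4
  expect_error(generate_library(5, 1, 1, seed = 1), "barcode space")
})

test_that("library TSV round-trips", {
  lib <- generate_library(4, 3, 12, seed = 2)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, fp)
  expect_identical(read_library(fp), lib)
})

test_that("a neutral screen keeps arm-wise proportions at baseline", {
  lib <- generate_library(50, 4, 14, seed = 3)
  role <- setNames(rep("neutral", 50), unique(lib$gene))
  s <- setNames(numeric(50), unique(lib$gene))
  eff <- setNames(runif(nrow(lib)), lib$shrna_id)
  tr <- screen_truth(role, s, eff)
  des <- screen_design(depth = 1e7, dispersion = 0, replicates = 1)
  cm <- simulate_screen(lib, tr, des, seed = 4)
  p <- sweep(cm$counts, 2, colSums(cm$counts), "/")
  ## all arms share the same expected composition
  expect_lt(max(abs(p[, "resistant_selected_rep1"] - p[, "reference_rep1"])),
            5e-4)
  expect_lt(max(abs(p[, "parental_acute_rep1"] - p[, "reference_rep1"])),
            5e-4)
})

test_that("a full-efficacy driver at s = -1/week drops 16-fold in the resistant arm only", {
  lib <- generate_library(200, 4, 14, seed = 5)
  genes <- unique(lib$gene)
  driver <- genes[1]
  role <- setNames(rep("neutral", length(genes)), genes)
  role[driver] <- "resistance_driver"
  s <- setNames(numeric(length(genes)), genes)
  s[driver] <- -1
  eff <- setNames(rep(1, nrow(lib)), lib$shrna_id)
  tr <- screen_truth(role, s, eff)
  cm <- simulate_screen(lib, tr,
                        screen_design(depth = 5e6, dispersion = 0.001,
                                      replicates = 3), seed = 6)
  norm <- cpm_normalize(cm)$counts
  idx <- lib$gene == driver
  ref <- rowMeans(norm[idx, cm$samples$arm == "reference", drop = FALSE])
  res <- rowMeans(norm[idx, cm$samples$arm == "resistant_selected",
                       drop = FALSE])
  acu <- rowMeans(norm[idx, cm$samples$arm == "parental_acute", drop = FALSE])
  expect_equal(mean(res / ref), 2^-4, tolerance = 0.1)
  expect_equal(mean(acu / ref), 1, tolerance = 0.1)
})

test_that("driver shRNA depletion matches the planted closed-form mean", {
  ## Monte-Carlo against 2^(s * efficacy * weeks), study-scale conditions
  for (seed in 1:3) {
    lib <- generate_library(100, 8, 18, seed = seed)
    tr <- random_screen_truth(lib, 10, 5, seed = seed + 10)
    cm <- simulate_screen(lib, tr, screen_design(), seed = seed + 20)
    norm <- cpm_normalize(cm)
    ids <- cm$samples$sample
    calls <- shrna_depletion(norm, ids[cm$samples$arm == "resistant_selected"],
                             ids[cm$samples$arm == "reference"],
                             pseudocount = 0)
    drivers <- names(tr$gene_role)[tr$gene_role == "resistance_driver"]
    idx <- calls$gene %in% drivers
    planted <- -0.75 * tr$efficacy[calls$shrna_id[idx]] * 4
    expect_lt(abs(mean(calls$lfc[idx]) - mean(planted)), 0.3)
  }
})

test_that("screen truth serialization round-trips losslessly", {
  lib <- generate_library(10, 3, 10, seed = 9)
  tr <- random_screen_truth(lib, 2, 1, seed = 11)
  fp <- withr::local_tempfile(fileext = ".json")
  write_screen_truth(tr, fp)
  back <- read_screen_truth(fp)
  expect_equal(back$gene_role, tr$gene_role)
  expect_equal(back$selection_coeff, tr$selection_coeff)
  expect_equal(back$efficacy, tr$efficacy)
})

test_that("screen truth validation rejects inconsistent inputs", {
  expect_error(screen_truth(c(g1 = "neutral"), c(g1 = -1), c(s1 = 0.5)),
               "selection_coeff 0")
  expect_error(screen_truth(c(g1 = "driver"), c(g1 = 0), c(s1 = 0.5)),
               "gene_role")
  lib <- generate_library(5, 2, 8, seed = 1)
  tr <- random_screen_truth(lib, 1, 1, seed = 1)
  tr$efficacy <- tr$efficacy[-1]
  expect_error(simulate_screen(lib, tr), "missing efficac")
})

test_that("RNA-seq simulation honors the null, planted effects, and the seed", {
  genes <- sprintf("g%03d", 1:300)
  base <- setNames(rep(100, 300), genes)
  eff <- matrix(0, 300, 2, dimnames = list(genes, c("ctl", "kd")))
  tr <- expression_truth(base, eff)
  cm <- simulate_rnaseq(tr, n_replicates = 6, dispersion = 0, seed = 12)
  a <- rowMeans(cm$counts[, cm$samples$group == "ctl"])
  b <- rowMeans(cm$counts[, cm$samples$group == "kd"])
  expect_equal(mean(b) / mean(a), 1, tolerance = 0.02)
  ## Poisson at phi = 0: variance tracks the mean across genes
  expect_equal(mean(apply(cm$counts, 1, var)) / mean(cm$counts), 1,
               tolerance = 0.15)
  expect_identical(simulate_rnaseq(tr, 3, 0.1, seed = 5)$counts,
                   simulate_rnaseq(tr, 3, 0.1, seed = 5)$counts)
  expect_error(simulate_rnaseq(tr, 3, -0.1, seed = 5), "dispersion")
  eff2 <- eff; eff2[1:50, "kd"] <- 1
  cm2 <- simulate_rnaseq(expression_truth(base, eff2), 50, 0.05, seed = 13)
  lfc <- log2(rowMeans(cm2$counts[1:50, cm2$samples$group == "kd"]) /
              rowMeans(cm2$counts[1:50, cm2$samples$group == "ctl"]))
  expect_equal(mean(lfc), 1, tolerance = 0.1)
})
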