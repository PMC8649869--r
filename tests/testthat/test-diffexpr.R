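sim_null <- function(n_genes, n_rep, phi, seed, meanlog = 5.5) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- setNames(withr::with_seed(seed, rlnorm(n_genes, meanlog, 1)), genes)
  eff <- matrix(0, n_genes, 2, dimnames = list(genes, c("A", "B")))
  simulate_rnaseq(expression_truth(base, eff), n_rep, phi, seed = seed + 1)
}

test_that("size factors satisfy the scaling identities and the brute-force oracle", {
  m <- matrix(rpois(200, 50) + 1, 100, 2,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b")))
  m[, 2] <- m[, 1]
  sf <- size_factors(count_matrix(m))
  expect_equal(unname(sf), c(1, 1))
  m[, 2] <- 2 * m[, 1]
  sf <- size_factors(count_matrix(m))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)
  set.seed(7)
  m2 <- matrix(rnbinom(500 * 5, mu = 100, size = 5), 500, 5,
               dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:5)))
  expect_equal(unname(size_factors(count_matrix(m2))),
               unname(oracle_median_of_ratios(m2)))
  ## independent route: DESeq2's median-of-ratios agrees up to centering
  ## (DESeq2 medians log-ratios, so agreement is near-exact, not bitwise)
  d <- DESeq2::estimateSizeFactorsForMatrix(m2)
  expect_equal(unname(size_factors(count_matrix(m2))),
               unname(d / exp(mean(log(d)))), tolerance = 1e-5)
  m3 <- diag(5); rownames(m3) <- sprintf("g%d", 1:5)
  colnames(m3) <- sprintf("s%d", 1:5)
  expect_error(size_factors(count_matrix(m3)), "positive in all samples")
})

test_that("dispersion estimation shrinks exactly as stated and recovers phi", {
  ## constant counts within groups: raw phi = 0, estimate = w * common
  m <- cbind(a1 = c(10, 100), a2 = c(10, 100),
             b1 = c(20, 50), b2 = c(20, 50))
  rownames(m) <- c("g1", "g2")
  cm <- count_matrix(m, normalized = TRUE)
  ## inject one dispersed gene so the common value is positive
  m2 <- rbind(m, g3 = c(5, 95, 10, 90))
  cm2 <- count_matrix(m2, normalized = TRUE)
  grp <- c("A", "A", "B", "B")
  for (w in c(0.3, 0.7)) {
    ph <- estimate_dispersion(cm2, grp, w = w)
    expect_equal(unname(ph[c("g1", "g2")]),
                 rep(w * attr(ph, "common"), 2))
  }
  ## Poisson data: median estimate collapses toward 0
  cmp <- sim_null(800, 10, 0, seed = 3)
  sf <- size_factors(cmp)
  php <- estimate_dispersion(
    count_matrix(sweep(cmp$counts, 2, sf, `/`), normalized = TRUE),
    cmp$samples$group)
  expect_lt(median(php), 0.02)
  ## NB at phi = 0.1, n = 10 per group: median within the recovery band
  cmn <- sim_null(2000, 10, 0.1, seed = 11)
  sfn <- size_factors(cmn)
  phn <- estimate_dispersion(
    count_matrix(sweep(cmn$counts, 2, sfn, `/`), normalized = TRUE),
    cmn$samples$group)
  expect_gt(median(phn), 0.05)
  expect_lt(median(phn), 0.2)
  expect_error(estimate_dispersion(cm, c("A", "B", "C", "D")), "replicates")
})

test_that("the NB test is null-centered, antisymmetric under label swap, and Poisson-limited", {
  cm <- sim_null(300, 3, 0.1, seed = 21)
  grp <- cm$samples$group
  ## identical groups: duplicate the same columns under two labels
  dup <- cm$counts[, c(1:3, 1:3)]
  colnames(dup) <- sprintf("s%d", 1:6)
  de0 <- nb_test(count_matrix(dup), c("A", "A", "A", "B", "B", "B"))
  expect_equal(de0$log2fc, rep(0, nrow(de0)))
  expect_true(all(de0$pvalue > 0.999))
  ## label-swap antisymmetry
  de1 <- nb_test(cm, grp)
  de2 <- nb_test(cm, ifelse(grp == "A", "B", "A"))
  expect_equal(de1$log2fc, -de2$log2fc, tolerance = 1e-9)
  expect_equal(de1$pvalue, de2$pvalue, tolerance = 1e-9)
  expect_true(all(de1$padj >= de1$pvalue))
  ## Poisson limit: at phi = 0 the LRT equals a directly coded Poisson LRT
  cmp <- sim_null(200, 3, 0, seed = 31)
  sf <- size_factors(cmp)
  phi0 <- setNames(rep(0, 200), rownames(cmp$counts))
  dep <- nb_test(cmp, cmp$samples$group, dispersion = phi0, sf = sf)
  stat <- qchisq(dep$pvalue, 1, lower.tail = FALSE)
  brute <- sapply(seq_len(200), function(i)
    oracle_poisson_lrt(cmp$counts[i, ], sf, cmp$samples$group))
  expect_equal(stat, pmax(brute, 0), tolerance = 1e-6)
  expect_error(nb_test(cm, rep("A", 6)), "two groups")
})

test_that("a planted 2-fold effect is recovered with significance", {
  lfc <- numeric(0); pv <- numeric(0)
  for (seed in 1:3) {
    genes <- sprintf("g%03d", 1:400)
    base <- setNames(withr::with_seed(seed, rlnorm(400, 5.5, 1)), genes)
    base["g001"] <- 500
    eff <- matrix(0, 400, 2, dimnames = list(genes, c("A", "B")))
    eff["g001", "B"] <- 1
    cm <- simulate_rnaseq(expression_truth(base, eff), 8, 0.1,
                          seed = 100 + seed)
    de <- nb_test(cm, cm$samples$group)
    row <- de[de$gene == "g001", ]
    lfc <- c(lfc, row$log2fc); pv <- c(pv, row$pvalue)
  }
  expect_lt(abs(mean(lfc) - 1), 0.25)
  expect_gte(sum(pv < 0.01), 2)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("the significance filter applies strict p and inclusive lfc boundaries", {
  res <- data.frame(
    gene = sprintf("g%02d", 1:10),
    base_mean = 100,
    log2fc = c(0.60, 2.0, 0.58, -0.58, 0.57, -3, 0.9, -0.59, 0.58, 1),
    pvalue = c(0.04, 0.05, 0.049, 0.001, 0.01, 0.02, 0.2, 0.04, 0.05, 1e-5),
    padj = 1, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  sets <- filter_de(res)
  ## hand enumeration: p < 0.05 strictly, |lfc| >= 0.58 inclusive
  expect_equal(sets$up, c("g01", "g03", "g05", "g10")[c(1, 2, 4)])
  expect_equal(sets$down, c("g04", "g06", "g08"))
  ## p exactly 0.05 excluded even at huge fold change
  expect_false("g02" %in% c(sets$up, sets$down))
  expect_false("g09" %in% sets$up)
  ## |lfc| = 0.58 included
  expect_true("g03" %in% sets$up)
  expect_true("g04" %in% sets$down)
  sets_fdr <- filter_de(res, use_fdr = TRUE)
  expect_equal(length(sets_fdr$up) + length(sets_fdr$down), 0)
})
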