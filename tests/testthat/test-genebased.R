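test_that("gene windows are inclusive at exactly 30 kb", {
  genes <- data.frame(gene_id = "G1", chrom = "1", tx_start = 100000L,
                      tx_end = 110000L, strand = "+")
  snps <- data.frame(snp_id = c("a", "b", "c", "d", "e"),
                     chrom = "1",
                     pos = c(70000L,        # tx_start - 30000: in
                             69999L,        # tx_start - 30001: out
                             105000L,       # inside the transcript: in
                             140000L,       # tx_end + 30000: in
                             140001L))      # out
  a <- assignSnpsToGenes(snps, genes, window = 30000L)
  expect_equal(snps$snp_id[a$G1], c("a", "c", "d"))
})

test_that("readGeneModels converts BED half-open to 1-based inclusive", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tGENEA\t0\t+",
               "chr2\t0\t500\tGENEB\t0\t-"), bed)
  g <- readGeneModels(bed, format = "bed")
  expect_equal(g$tx_start, c(1000L, 1L))
  expect_equal(g$tx_end, c(2000L, 500L))
  expect_equal(g$chrom, c("1", "2"))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstart\tend", "GENEC\t3\t100\t200"), tsv)
  g2 <- readGeneModels(tsv, format = "tsv")
  expect_equal(g2$tx_start, 100L)
})

test_that("ldFromGenotypes builds valid shrunk correlation matrices", {
  set.seed(2)
  X <- matrix(rbinom(400 * 5, 2, 0.3), 400, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  X <- cbind(X, s6 = X[, 5])  # perfect LD pair
  ld <- ldFromGenotypes(X)
  expect_equal(ld@R["s5", "s6"], 1, tolerance = 1e-6)
  ev <- eigen(ld@R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)

  # independent columns: off-diagonals near zero at large n
  set.seed(3)
  Y <- matrix(rbinom(1e4 * 4, 2, 0.4), 1e4, 4)
  ld2 <- ldFromGenotypes(Y)
  off <- ld2@R[upper.tri(ld2@R)]
  expect_lt(max(abs(off)), 0.03)

  Xm <- cbind(X, mono = rep(1, 400))
  expect_error(ldFromGenotypes(Xm), "mono")
})

test_that("geneStatistic sums 1-df chi-square quantiles", {
  expect_equal(geneStatistic(0.5), 0.4549364, tolerance = 1e-6)
  expect_equal(geneStatistic(0.05), 3.841459, tolerance = 1e-6)
  expect_equal(geneStatistic(c(0.5, 0.5)), 2 * 0.4549364,
               tolerance = 1e-6)
  expect_error(geneStatistic(numeric(0)), "empty")
  expect_error(geneStatistic(c(0.5, 0)), "p-values")
})

test_that("geneEmpiricalP matches analytic tails for identity and rank-1 LD", {
  # single SNP with p = 0.05: empirical p within 3 MC SEs of 0.05
  nSim <- 1e4
  r <- geneEmpiricalP(geneStatistic(0.05), matrix(1, 1, 1),
                      stages = c(1e3, nSim), seed = 31)
  se <- sqrt(0.05 * 0.95 / r$n_sims_final)
  expect_lt(abs(r$empirical_p - 0.05), 3 * se)

  # two SNPs in perfect LD, each p = 0.05: Q ~ 2*chi2_1, tail still 0.05
  Q2 <- geneStatistic(c(0.05, 0.05))
  expect_equal(Q2, 7.682918, tolerance = 1e-5)
  r2 <- geneEmpiricalP(Q2, matrix(1, 2, 2), stages = c(1e3, nSim),
                       seed = 32)
  se2 <- sqrt(0.05 * 0.95 / r2$n_sims_final)
  expect_lt(abs(r2$empirical_p - 0.05), 3 * se2)

  # identity LD with 5 SNPs: tail is chi-square on 5 df
  Q5 <- 9.2
  pTrue <- pchisq(Q5, 5, lower.tail = FALSE)
  r5 <- geneEmpiricalP(Q5, diag(5), stages = c(1e3, nSim), seed = 33)
  se5 <- sqrt(pTrue * (1 - pTrue) / r5$n_sims_final)
  expect_lt(abs(r5$empirical_p - pTrue), 3 * se5)
})

test_that("empirical p is monotone in Q, deterministic, and floored", {
  R <- equicorr(3, 0.5)
  qs <- c(1, 5, 10, 20)
  ps <- vapply(qs, function(q)
    geneEmpiricalP(q, R, stages = c(1e3, 1e4), seed = 41)$empirical_p,
    numeric(1))
  expect_true(all(diff(ps) <= 0))
  a <- geneEmpiricalP(7, R, stages = c(1e3, 1e4), seed = 42)
  b <- geneEmpiricalP(7, R, stages = c(1e3, 1e4), seed = 42)
  expect_identical(a, b)
  # permutation-count floor: p * (n_sims + 1) >= 1
  big <- geneEmpiricalP(1e6, R, stages = c(1e3, 1e4), seed = 43)
  expect_gte(big$empirical_p * (big$n_sims_final + 1), 1)
  expect_equal(big$n_exceed, 0L)
})

test_that("adaptive staging stops once 10 exceedances are seen", {
  r <- geneEmpiricalP(0.1, diag(2), stages = c(1e3, 1e4, 1e6), seed = 44)
  expect_equal(r$n_sims_final, 1000L)  # common Q exceeded at stage one
  expect_gte(r$n_exceed, 10L)
})

test_that("bonferroniThreshold reproduces printed gene- and test-wide levels", {
  expect_equal(attr(bonferroniThreshold(0.05, 18500), "display"), 2.70e-6)
  expect_equal(attr(bonferroniThreshold(0.05, 22), "display"), 2.27e-3)
  expect_equal(attr(bonferroniThreshold(0.05, 127), "display"), 3.94e-4)
  expect_equal(as.numeric(bonferroniThreshold(0.05, 1)), 0.05)
})

test_that("geneBasedScan runs gene windows end to end on generated data", {
  g <- simulateGenotypes(300, 40, blockSize = 10, rhoWithin = 0.6,
                         seed = 51)
  snps <- g$snpMap
  genes <- data.frame(gene_id = c("G1", "G2", "Gempty"),
                      chrom = c(snps$chrom[1], snps$chrom[11], "9"),
                      tx_start = c(snps$pos[1], snps$pos[11], 5L),
                      tx_end = c(snps$pos[5], snps$pos[15], 10L),
                      strand = "*")
  scan <- data.frame(snps[, c("snp_id", "chrom", "pos")],
                     p_joint = runif(40, 0.2, 1))
  res <- geneBasedScan(scan, genes, g$dosages, seed = 52,
                       stages = c(1e3, 1e4))
  expect_equal(sort(res$gene_id), c("G1", "G2"))
  expect_true(all(res$empirical_p > 0 & res$empirical_p <= 1))
  expect_true("Gempty" %in% attr(res, "skipped"))
})
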