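test_that("simulateGenotypes is seed-deterministic with controlled MAF and LD", {
  g1 <- simulateGenotypes(500, 60, blockSize = 20, rhoWithin = 0.9,
                          seed = 71)
  g2 <- simulateGenotypes(500, 60, blockSize = 20, rhoWithin = 0.9,
                          seed = 71)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))

  # sample MAF tracks the drawn MAF at n = 5000
  g <- simulateGenotypes(5000, 100, blockSize = 10, rhoWithin = 0.5,
                         seed = 72)
  sampleMaf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  drawn <- pmin(g$snpMap$maf, 1 - g$snpMap$maf)
  expect_lt(max(abs(sampleMaf - drawn)), 0.02)

  # strong within-block latent correlation survives dosage thresholding
  gHi <- simulateGenotypes(5000, 40, blockSize = 20, rhoWithin = 0.9,
                           mafRange = c(0.3, 0.5), seed = 73)
  adj <- sapply(seq_len(19), function(j)
    cor(gHi$dosages[, j], gHi$dosages[, j + 1]))
  expect_gt(min(adj), 0.6)

  # rho = 0: adjacent dosage correlation is sampling noise
  g0 <- simulateGenotypes(5000, 40, blockSize = 20, rhoWithin = 0,
                          seed = 74)
  adj0 <- sapply(seq_len(19), function(j)
    cor(g0$dosages[, j], g0$dosages[, j + 1]))
  expect_lt(max(abs(adj0)), 3 / sqrt(5000) * 1.5)
})

test_that("null traits realize the target score correlations at n = 4000", {
  g <- simulateGenotypes(4000, 20, seed = 75)
  tr <- simulateTraits(g$dosages, NULL, seed = 76)
  ph <- tr$phenotypes
  expect_true(all(ph$NP %in% 0:3) && all(ph$NFT %in% 0:3))
  expect_true(all(ph$CAA %in% 0:1))
  expect_lt(abs(cor(ph$NP, ph$NFT) - 0.68), 0.05)
  expect_lt(abs(cor(ph$NP, ph$CAA) - 0.56), 0.05)
  expect_lt(abs(cor(ph$NFT, ph$CAA) - 0.40), 0.05)
  expect_equal(mean(ph$status == "AD"), 0.87, tolerance = 0.01)
})

test_that("a single-trait causal SNP moves only its own trait", {
  g <- simulateGenotypes(3000, 10, blockSize = 1, seed = 77)
  eff <- data.frame(snp_id = g$snpMap$snp_id[1], NP = 0.5, NFT = 0,
                    CAA = 0)
  tr <- simulateTraits(g$dosages, eff, seed = 78)
  dos <- g$dosages[, 1]
  pNP <- kruskal.test(dos, factor(tr$phenotypes$NP))$p.value
  expect_lt(pNP, 0.01)
  # NFT is associated only through the residual correlation with NP;
  # compare against an unrelated SNP to bound spurious association
  f <- fitSumStats(g$dosages, tr$phenotypes, g$snpMap,
                   models = c(NFT = "proportional_odds"))
  zNFT <- with(records(f$NFT), beta / se)
  expect_gt(abs(zNFT[1]), 0)  # defined
  expect_lt(abs(zNFT[1]), abs(qnorm(1e-12)))  # far weaker than NP signal
  fNP <- fitSumStats(g$dosages, tr$phenotypes, g$snpMap,
                     models = c(NP = "proportional_odds"))
  zNP <- with(records(fNP$NP), beta / se)
  expect_gt(abs(zNP[1]), 2 * abs(zNFT[1]))
})

test_that("degenerate single-level traits are rejected by the fitter", {
  g <- simulateGenotypes(200, 5, seed = 79)
  cuts <- list(NP = c(Inf, Inf, Inf), NFT = qnorm(c(0.25, 0.5, 0.75)),
               CAA = 0)
  tr <- simulateTraits(g$dosages, NULL, cutpoints = cuts,
                       targetCorr = c(np_nft = 0, np_caa = 0,
                                      nft_caa = 0.4), seed = 80)
  expect_true(all(tr$phenotypes$NP == 0))
  expect_error(fitSumStats(g$dosages, tr$phenotypes, g$snpMap,
                           models = c(NP = "proportional_odds")),
               "degenerate")
})

test_that("the proportional-odds Newton fitter matches MASS::polr", {
  set.seed(81)
  for (i in 1:5) {
    n <- 800
    x <- rbinom(n, 2, runif(1, 0.15, 0.45))
    y <- as.integer(cut(runif(1, -0.3, 0.5) * x + rlogis(n),
                        c(-Inf, -0.5, 0.5, 1.5, Inf)))
    f <- fitPropOdds(y, x)
    ref <- MASS::polr(factor(y, ordered = TRUE) ~ x, Hess = TRUE)
    expect_true(f$converged)
    expect_equal(f$beta, unname(coef(ref)), tolerance = 1e-4)
    expect_equal(f$se, sqrt(vcov(ref)[1, 1]), tolerance = 1e-3)
  }
})

test_that("the logistic SNP fitter matches glm", {
  set.seed(82)
  n <- 700
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  f <- pleioscan:::.fitLogistic(y, x)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(f$beta, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(f$se, unname(sqrt(vcov(ref)[2, 2])), tolerance = 1e-6)
})

test_that("null GWAS p-values from the ordinal and logistic fits are uniform", {
  set.seed(83)
  nRep <- 400
  n <- 1000
  pOrd <- pBin <- numeric(nRep)
  for (i in seq_len(nRep)) {
    x <- rbinom(n, 2, 0.3)
    yOrd <- as.integer(cut(rlogis(n), c(-Inf, -1, 0.5, 2, Inf)))
    f <- fitPropOdds(yOrd, x)
    pOrd[i] <- 2 * pnorm(-abs(f$beta / f$se))
    yBin <- rbinom(n, 1, 0.5)
    fb <- pleioscan:::.fitLogistic(yBin, x)
    pBin[i] <- 2 * pnorm(-abs(fb$beta / fb$se))
  }
  expect_gt(ks.test(pOrd, "punif")$p.value, 0.01)
  expect_gt(ks.test(pBin, "punif")$p.value, 0.01)
  # null logistic betas center on zero
  expect_lt(abs(mean(pBin < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / nRep))
})

test_that("simulateZDirect is deterministic and recovers its covariance", {
  S <- equicorr(3, 0.4)
  z1 <- simulateZDirect(1000, S, seed = 84)
  z2 <- simulateZDirect(1000, S, seed = 84)
  expect_identical(z1@z, z2@z)
  zBig <- simulateZDirect(1e5, S, seed = 85)
  Sh <- covMatrix(estimateCovariance(zBig))
  expect_lt(max(abs(Sh - S)), 0.01)
})

test_that("joint-test power beats univariate power for shared signals", {
  S <- equicorr(2, 0.4)
  Z <- simulateZDirect(1000, S, signalFraction = 1, signalSize = 4,
                       seed = 86)
  sc <- jointScan(Z, S, traits = traitLabels(Z))
  alpha <- 1e-6
  powJoint <- mean(sc$p_joint < alpha)
  powUni <- mean(sc[[paste0("p_", traitLabels(Z)[1])]] < alpha)
  expect_gt(powJoint, powUni)
})

test_that("whole studies serialize their ground truth and round trip to disk", {
  st <- simulateStudy(n = 300, M = 200, nDual = 2, nSingle = 2,
                      blockSize = 20, seed = 87)
  expect_s4_class(st, "SyntheticStudy")
  expect_equal(nrow(st@truth$causal), 4L)
  expect_setequal(unique(st@truth$causal$type), c("dual", "single"))
  # causal SNPs land in distinct LD blocks
  blk <- st@snpMap$block[match(st@truth$causal$snp_id, st@snpMap$snp_id)]
  expect_equal(anyDuplicated(blk), 0L)

  dir <- tempfile("study_")
  paths <- writeStudy(st, dir)
  expect_true(all(file.exists(paths)))
  dos <- readDosages(paths["dosages"], format = "table")
  expect_equal(unname(dos[3, 5]), unname(st@dosages[3, 5]))
  vdos <- readDosages(paths["panel_vcf"], format = "vcf")
  expect_equal(unname(vdos[, st@snpMap$snp_id[1]]),
               unname(st@dosages[, 1]))
})

test_that("expression generator truth behaves under zero effects", {
  se <- simulateExpression(nGenes = 50, nSamples = 150, seed = 88)
  ps <- vapply(sprintf("gene%04d", 1:50), function(g)
    dgeLm(se, g)$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
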