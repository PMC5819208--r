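test_that("estimateCovariance recovers degenerate and simulated structure", {
  set.seed(1)
  z1 <- rnorm(500)
  Z <- cbind(A = z1, B = z1)
  S <- estimateCovariance(Z)
  expect_equal(covMatrix(S)[1, 2], covMatrix(S)[1, 1], tolerance = 1e-6)

  # independent pairs: off-diagonal within the 3/sqrt(M) sampling bound
  M <- 1e5
  Z0 <- matrix(rnorm(2 * M), M, 2, dimnames = list(NULL, c("A", "B")))
  S0 <- estimateCovariance(Z0)
  expect_lt(abs(covMatrix(S0)[1, 2]), 3 / sqrt(M))

  # correlated nulls: recovery within 0.01
  Zc <- simulateZDirect(M, equicorr(2, 0.6), seed = 7)
  Sc <- estimateCovariance(Zc)
  expect_equal(covMatrix(Sc)[1, 2], 0.6, tolerance = 0.01)

  expect_error(estimateCovariance(matrix(rnorm(30), 15, 2)), "SNP rows")
})

test_that("truncated covariance mode drops extreme rows and stays valid", {
  Z <- simulateZDirect(5e4, equicorr(2, 0.4), signalFraction = 0.01,
                       signalSize = 8, seed = 3)
  St <- estimateCovariance(Z, mode = "truncated", zCap = 2)
  expect_s4_class(St, "TestCovariance")
  expect_lt(St@nSnps, 5e4)
  expect_equal(St@mode, "truncated")
})

test_that("obrienStatistic matches closed-form cases for both weightings", {
  # K = 1 reduces to the univariate statistic
  expect_equal(obrienStatistic(2.0, matrix(1)), 2.0)
  # identity covariance
  expect_equal(obrienStatistic(c(1.96, 1.96), diag(2)), 3.92 / sqrt(2),
               tolerance = 1e-12)
  # equicorrelated rho = 0.68: T = 9.55/sqrt(3.36), same for both weights
  S <- equicorr(2, 0.68)
  tGls <- obrienStatistic(c(4.95, 4.60), S, "gls")
  tEq <- obrienStatistic(c(4.95, 4.60), S, "equal")
  expect_equal(tGls, 9.55 / sqrt(3.36), tolerance = 1e-12)
  expect_equal(tGls, tEq, tolerance = 1e-12)
  expect_equal(2 * pnorm(-tGls), 1.9e-7, tolerance = 0.01)
})

test_that("gls and equal weights agree to 1e-10 on any equicorrelated Sigma", {
  set.seed(11)
  for (i in 1:50) {
    K <- sample(2:4, 1)
    S <- equicorr(K, runif(1, -0.2, 0.9))
    z <- rnorm(K, sd = 2)
    expect_equal(obrienStatistic(z, S, "gls"),
                 obrienStatistic(z, S, "equal"), tolerance = 1e-10)
  }
})

test_that("the combined test is equivariant under consistent rescaling", {
  # scaling the statistics by sqrt(c) and the covariance by c leaves T
  # unchanged (the self-consistency that makes the scale of Sigma
  # immaterial in the pipeline, where Sigma is estimated from Z itself)
  set.seed(4)
  for (i in 1:20) {
    K <- 3
    A <- matrix(rnorm(K * K), K)
    S <- crossprod(A) + diag(K)
    z <- rnorm(K)
    cc <- runif(1, 0.1, 10)
    expect_equal(obrienStatistic(z, S),
                 obrienStatistic(sqrt(cc) * z, cc * S), tolerance = 1e-10)
  }
})

test_that("jointScan is row-wise consistent and reduces to univariate at K=1", {
  Z <- simulateZDirect(500, equicorr(3, 0.4), seed = 5)
  colnames(Z@z) <- Z@traits <- c("NP", "NFT", "CAA")
  Sig <- estimateCovariance(Z)
  sc <- jointScan(Z, Sig, traits = c("NP", "NFT"))
  S2 <- covMatrix(Sig)[c("NP", "NFT"), c("NP", "NFT")]
  for (i in c(1, 100, 500))
    expect_equal(sc$t_joint[i],
                 obrienStatistic(Z@z[i, c("NP", "NFT")], S2),
                 tolerance = 1e-12)
  sc1 <- jointScan(Z, Sig, traits = "CAA")
  expect_equal(sc1$p_joint, sc1$p_CAA, tolerance = 1e-12)
  expect_error(jointScan(Z, Sig, traits = c("NP", "XX")), "XX")
  expect_error(jointScan(Z, Sig, traits = c("NP", "NP")), "duplicated")
})

test_that("joint test keeps nominal size on null draws", {
  M <- 2e4
  Z <- simulateZDirect(M, equicorr(2, 0.4), seed = 9)
  sc <- jointScan(Z, estimateCovariance(Z), traits = traitLabels(Z))
  frac <- mean(sc$p_joint < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / M))
})

test_that("classifyPleiotropy reproduces the declaration-rule cases", {
  # GWS pleiotropic: joint far below both univariate/10, both nominal
  expect_equal(as.character(
    classifyPleiotropy(1.1e-8, matrix(c(2.3e-5, 9.1e-6), 1))),
    "gws_pleiotropic")
  # second trait fails nominal significance
  expect_equal(as.character(
    classifyPleiotropy(2.5e-6, matrix(c(7.7e-7, 0.06), 1))),
    "not_pleiotropic")
  # one trait non-significant, joint above p2/10
  expect_equal(as.character(
    classifyPleiotropy(1e-9, matrix(c(0.5, 1e-10), 1))),
    "not_pleiotropic")
  # pleiotropic but not GWS
  expect_equal(as.character(
    classifyPleiotropy(1e-4, matrix(c(1e-3, 2e-3), 1))),
    "pleiotropic")
  # boundary: non-strict magnitude comparison
  expect_equal(as.character(
    classifyPleiotropy(1e-4, matrix(c(1e-3, 1e-3), 1))),
    "pleiotropic")
  expect_error(classifyPleiotropy(0, matrix(c(0.5, 0.5), 1)), "p-values")
})

test_that("genomicLambda matches its closed form and honors exclusions", {
  expect_equal(genomicLambda(rep(0.5, 11)), 1.0, tolerance = 1e-12)
  # p-values whose median 1-df chi-square is 0.9098728 give lambda = 2
  p2 <- rep(pchisq(2 * qchisq(0.5, 1), 1, lower.tail = FALSE), 5)
  expect_equal(genomicLambda(p2), 2.0, tolerance = 1e-6)
  # exclusion region containing no SNPs is a no-op
  p <- runif(100)
  chrom <- rep("1", 100)
  pos <- seq_len(100)
  expect_equal(
    genomicLambda(p, excludeRegion = list(chrom = "19", start = 1,
                                          end = 100),
                  chrom = chrom, pos = pos),
    genomicLambda(p))
  # excluding an inflated region moves lambda toward 1
  pInfl <- c(runif(1000), rep(1e-10, 200))
  chrom <- c(rep("1", 1000), rep("19", 200))
  pos <- c(seq_len(1000), seq(44.5e6, by = 10, length.out = 200))
  lamAll <- genomicLambda(pInfl)
  lamExcl <- genomicLambda(pInfl, excludeRegion = apoeRegion(),
                           chrom = chrom, pos = pos)
  expect_lt(lamExcl, lamAll)
  expect_error(genomicLambda(numeric(0)), "empty")
})

test_that("qqTable pairs sorted observed with uniform expected quantiles", {
  q1 <- qqTable(0.5)
  expect_equal(q1$expected, -log10(0.5), tolerance = 1e-6)
  expect_equal(q1$observed, -log10(0.5), tolerance = 1e-6)
  expect_equal(round(q1$expected, 3), 0.301)
  # uniform p-values track the diagonal within the Kolmogorov bound
  set.seed(21)
  p <- runif(5000)
  q <- qqTable(p)
  dev <- max(abs(10^(-q$observed) - 10^(-q$expected)))
  expect_lt(dev, 1.949 / sqrt(5000))  # 0.1% Kolmogorov critical value
  # duplicates allowed, length preserved
  expect_equal(nrow(qqTable(c(0.1, 0.1, 0.9))), 3L)
})

test_that("joint p is stochastically smaller than univariate p for shared effects", {
  # equal standardized effects on both traits, rho < 1
  Z <- simulateZDirect(500, equicorr(2, 0.4), signalFraction = 1,
                       signalSize = 3, seed = 13)
  sc <- jointScan(Z, equicorr(2, 0.4), traits = traitLabels(Z))
  expect_lt(median(sc$p_joint), median(sc[[paste0("p_", traitLabels(Z)[1])]]))
  expect_lt(median(sc$p_joint), median(sc[[paste0("p_", traitLabels(Z)[2])]]))
})

test_that("trivariate p attenuates when only two of three traits carry the effect", {
  S3 <- equicorr(3, 0.4)
  Z <- simulateZDirect(600, S3, signalFraction = 1, signalSize = 4,
                       signalTraits = c("Z1", "Z2"), seed = 17)
  scTri <- jointScan(Z, S3, traits = c("Z1", "Z2", "Z3"))
  scBiv <- jointScan(Z, S3, traits = c("Z1", "Z2"))
  expect_gt(median(scTri$p_joint), median(scBiv$p_joint))
})
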