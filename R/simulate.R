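## ---- genotypes ----------------------------------------------------------

.ar1 <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))

#' Simulate LD-blocked genotype dosages
#'
#' Haplotypes are thresholded latent Gaussians with AR(1) correlation
#' \code{rhoWithin} inside blocks of \code{blockSize} SNPs and independence
#' across blocks; an allele is carried when the latent exceeds the
#' MAF-matched quantile, and the dosage is the sum over the two haplotypes,
#' so each SNP is in Hardy-Weinberg proportions at its drawn MAF. Blocks
#' are laid out cyclically over chromosomes 1-22 with 1 kb SNP spacing.
#'
#' @param n subjects.
#' @param M SNPs.
#' @param mafRange range minor-allele frequencies are drawn uniformly from.
#' @param blockSize SNPs per LD block.
#' @param rhoWithin latent AR(1) correlation inside a block, in [0, 1).
#' @param seed integer seed.
#' @return list with \code{dosages} (n x M, colnames = snp ids) and
#'   \code{snpMap} (snp_id, chrom, pos, effect_allele, ref_allele, maf,
#'   block).
#' @export
simulateGenotypes <- function(n, M, mafRange = c(0.01, 0.5),
                              blockSize = 50L, rhoWithin = 0.8, seed) {
  stopifnot(rhoWithin >= 0, rhoWithin < 1, n >= 2, M >= 1,
            !missing(seed))
  set.seed(as.integer(seed))
  maf <- runif(M, mafRange[1], mafRange[2])
  thr <- qnorm(1 - maf)
  blocks <- rep(seq_len(ceiling(M / blockSize)), each = blockSize)[1:M]
  dos <- matrix(0L, n, M)
  for (b in unique(blocks)) {
    ix <- which(blocks == b)
    p <- length(ix)
    U <- chol(.ar1(p, rhoWithin))
    h1 <- matrix(rnorm(n * p), n, p) %*% U
    h2 <- matrix(rnorm(n * p), n, p) %*% U
    dos[, ix] <- (sweep(h1, 2, thr[ix], ">") +
                    sweep(h2, 2, thr[ix], ">"))
  }
  ids <- sprintf("snp%06d", seq_len(M))
  colnames(dos) <- ids
  nBlocks <- max(blocks)
  chrom <- as.character(((blocks - 1L) %% 22L) + 1L)
  ## position restarts per chromosome, 1 kb spacing
  pos <- integer(M)
  for (ch in unique(chrom)) {
    cix <- which(chrom == ch)
    pos[cix] <- 1000000L + 1000L * seq_along(cix)
  }
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  ai <- sample.int(4, M, replace = TRUE)
  snpMap <- data.frame(snp_id = ids, chrom = chrom, pos = pos,
                       effect_allele = pairs[ai, 1],
                       ref_allele = pairs[ai, 2],
                       maf = maf, block = blocks,
                       stringsAsFactors = FALSE)
  list(dosages = dos, snpMap = snpMap)
}

## ---- latent-correlation calibration ------------------------------------

## P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
## by 1-D quadrature (no bivariate-normal CDF dependency needed)
.bvnSurvival <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(-a) * pnorm(-b))
  f <- function(z) exp(dnorm(z, log = TRUE) +
                         pnorm((rho * z - b) / sqrt(1 - rho^2),
                               log.p = TRUE))
  integrate(f, lower = a, upper = max(a + 1, 9) + 30,
            rel.tol = 1e-10)$value
}

## expected Pearson correlation between the thresholded scores
## X = sum_k 1(Z1 > cuts1[k]), Y = sum_l 1(Z2 > cuts2[l])
.thresholdedPearson <- function(rho, cuts1, cuts2) {
  s1 <- pnorm(-cuts1); s2 <- pnorm(-cuts2)
  covXY <- 0
  for (a in cuts1) for (b in cuts2)
    covXY <- covXY + .bvnSurvival(a, b, rho) -
      pnorm(-a) * pnorm(-b)
  varOf <- function(cuts, s) {
    v <- 0
    for (i in seq_along(cuts)) for (j in seq_along(cuts))
      v <- v + pnorm(-max(cuts[i], cuts[j])) - s[i] * s[j]
    v
  }
  covXY / sqrt(varOf(cuts1, s1) * varOf(cuts2, s2))
}

#' Latent correlation needed to realize a target score correlation
#'
#' Solves for the latent bivariate-normal correlation such that the
#' Pearson correlation of the thresholded (ordinal or binary) scores
#' equals \code{target}, accounting for categorization attenuation.
#'
#' @param target target Pearson correlation of the realized scores.
#' @param cuts1,cuts2 threshold vectors of the two traits (one cut for a
#'   binary trait).
#' @return latent correlation (scalar).
#' @export
latentCorrFor <- function(target, cuts1, cuts2) {
  stopifnot(abs(target) < 1)
  if (abs(target) < 1e-12) return(0)
  uniroot(function(r) .thresholdedPearson(r, cuts1, cuts2) - target,
          interval = c(-0.995, 0.995), tol = 1e-6)$root
}

.DEFAULT_CUTS <- list(NP = qnorm(c(0.25, 0.5, 0.75)),
                      NFT = qnorm(c(0.25, 0.5, 0.75)),
                      CAA = 0)

.DEFAULT_TARGET_CORR <- c(np_nft = 0.68, np_caa = 0.56, nft_caa = 0.40)

## ---- traits -------------------------------------------------------------

#' Simulate correlated ordinal/binary neuropathological traits
#'
#' Liability-threshold generator: each trait's latent liability is the sum
#' of standardized-dosage causal effects and a correlated Gaussian
#' residual. NP and NFT are cut into 4 ordinal levels (0-3), CAA is
#' dichotomized at its threshold. When \code{residCorr} is \code{NULL} the
#' latent residual correlations are calibrated so the realized Pearson
#' correlations of the scores hit \code{targetCorr} (NP-NFT 0.68, NP-CAA
#' 0.56, NFT-CAA 0.40 by default). AD/control status is assigned by
#' thresholding a composite of the three liabilities so that a fraction
#' \code{adFraction} (default 0.87) of subjects are cases.
#'
#' @param dosages n x M dosage matrix.
#' @param causalEffects data.frame with \code{snp_id} and per-trait
#'   liability-scale effect columns \code{NP}, \code{NFT}, \code{CAA}
#'   (effects per standard deviation of dosage); NULL for a null study.
#' @param residCorr 3 x 3 latent residual correlation (NP, NFT, CAA), or
#'   NULL to calibrate from \code{targetCorr}.
#' @param cutpoints list of latent thresholds (defaults: quartile cuts for
#'   the ordinal traits, 0 for CAA).
#' @param targetCorr named target score correlations (used only when
#'   \code{residCorr} is NULL).
#' @param adFraction fraction of subjects labelled AD.
#' @param seed integer seed.
#' @return list: \code{phenotypes} (data.frame NP, NFT, CAA, status),
#'   \code{truth} (causal table + latent residual correlation used).
#' @export
simulateTraits <- function(dosages, causalEffects = NULL,
                           residCorr = NULL,
                           cutpoints = .DEFAULT_CUTS,
                           targetCorr = .DEFAULT_TARGET_CORR,
                           adFraction = 0.87, seed) {
  stopifnot(!missing(seed), adFraction > 0, adFraction < 1)
  n <- nrow(dosages)
  if (is.null(residCorr)) {
    r12 <- latentCorrFor(targetCorr[["np_nft"]], cutpoints$NP,
                         cutpoints$NFT)
    r13 <- latentCorrFor(targetCorr[["np_caa"]], cutpoints$NP,
                         cutpoints$CAA)
    r23 <- latentCorrFor(targetCorr[["nft_caa"]], cutpoints$NFT,
                         cutpoints$CAA)
    residCorr <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  }
  dimnames(residCorr) <- list(c("NP", "NFT", "CAA"), c("NP", "NFT", "CAA"))
  ev <- eigen(residCorr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("input error: residual correlation matrix is not positive definite")
  set.seed(as.integer(seed))
  E <- matrix(rnorm(n * 3), n, 3) %*% chol(residCorr)
  G <- matrix(0, n, 3)
  if (!is.null(causalEffects) && nrow(causalEffects)) {
    ix <- match(causalEffects$snp_id, colnames(dosages))
    if (anyNA(ix))
      stop("input error: causal snp_id absent from dosages: ",
           paste(causalEffects$snp_id[is.na(ix)], collapse = ", "))
    X <- scale(dosages[, ix, drop = FALSE])
    B <- as.matrix(causalEffects[, c("NP", "NFT", "CAA")])
    G <- X %*% B
  }
  L <- G + E
  cutTo <- function(l, cuts) {
    as.integer(rowSums(outer(l, cuts, ">")))
  }
  ph <- data.frame(NP = cutTo(L[, 1], cutpoints$NP),
                   NFT = cutTo(L[, 2], cutpoints$NFT),
                   CAA = as.integer(L[, 3] > cutpoints$CAA[1]))
  disease <- rowMeans(L) + 0.5 * rnorm(n)
  ph$status <- ifelse(disease > quantile(disease, 1 - adFraction),
                      "AD", "control")
  list(phenotypes = ph,
       truth = list(causal = causalEffects, residCorr = residCorr,
                    cutpoints = cutpoints))
}

## ---- fast ordinal / logistic GWAS fits ----------------------------------

#' Proportional-odds fit of an ordinal outcome on a single covariate
#'
#' Newton-Raphson maximum likelihood for the cumulative-logit
#' (proportional-odds) model \eqn{logit P(Y \le k) = \alpha_k - x\beta},
#' with analytic gradient and Hessian. Matches \code{MASS::polr} to
#' high precision while being fast enough for genome-wide per-SNP fits.
#'
#' @param y integer outcome with ordered levels 1..K (K >= 2).
#' @param x numeric covariate (e.g. a dosage).
#' @param maxit,tol Newton iteration controls.
#' @return list: \code{beta}, \code{se}, \code{alpha} (cutpoints),
#'   \code{converged}, \code{iter}.
#' @export
fitPropOdds <- function(y, x, maxit = 30L, tol = 1e-8) {
  y <- as.integer(y)
  K <- max(y)
  if (K < 2L || length(unique(y)) < 2L)
    stop("input error: ordinal outcome is degenerate (single level)")
  n <- length(y)
  stopifnot(length(x) == n, min(y) >= 1L)
  if (any(tabulate(y, K) == 0L))
    y <- match(y, sort(unique(y)))  # collapse unobserved levels
  K <- max(y)
  cnt <- tabulate(y, K)
  cum <- cumsum(cnt)[1:(K - 1)] / n
  theta <- c(qlogis(cum), 0)
  hiIdx <- pmin(y, K - 1L)  # alpha index for the upper bound (y < K)
  loIdx <- pmax(y - 1L, 1L)
  isTop <- y == K
  isBot <- y == 1L
  devAt <- function(th) {
    alpha <- th[1:(K - 1)]; beta <- th[K]
    etaHi <- ifelse(isTop, Inf, alpha[hiIdx] - x * beta)
    etaLo <- ifelse(isBot, -Inf, alpha[loIdx] - x * beta)
    pr <- pmax(plogis(etaHi) - plogis(etaLo), 1e-300)
    -2 * sum(log(pr))
  }
  dev <- devAt(theta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    alpha <- theta[1:(K - 1)]; beta <- theta[K]
    etaHi <- ifelse(isTop, Inf, alpha[hiIdx] - x * beta)
    etaLo <- ifelse(isBot, -Inf, alpha[loIdx] - x * beta)
    Fhi <- plogis(etaHi); Flo <- plogis(etaLo)
    pr <- pmax(Fhi - Flo, 1e-12)
    fhi <- Fhi * (1 - Fhi); flo <- Flo * (1 - Flo)
    fphi <- fhi * (1 - 2 * Fhi); fplo <- flo * (1 - 2 * Flo)
    dhi <- fhi / pr; dlo <- flo / pr
    hhh <- fphi / pr - dhi^2
    hll <- -fplo / pr - dlo^2
    hhl <- dhi * dlo
    g <- numeric(K)
    H <- matrix(0, K, K)
    for (k in seq_len(K - 1)) {
      inK <- y == k; inK1 <- y == (k + 1L)
      g[k] <- sum(dhi[inK]) - sum(dlo[inK1])
      H[k, k] <- sum(hhh[inK]) + sum(hll[inK1])
      if (k < K - 1) {
        H[k, k + 1] <- H[k + 1, k] <- sum(hhl[inK1])
      }
      hb <- -sum(x[inK] * (hhh[inK] + hhl[inK])) -
        sum(x[inK1] * (hll[inK1] + hhl[inK1]))
      H[k, K] <- H[K, k] <- hb
    }
    g[K] <- sum(x * (dlo - dhi))
    H[K, K] <- sum(x^2 * (hhh + hll + 2 * hhl))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    newTheta <- theta - step
    newDev <- devAt(newTheta)
    halv <- 0L
    while ((!is.finite(newDev) || newDev > dev + 1e-10 ||
            is.unsorted(newTheta[1:(K - 1)], strictly = TRUE)) &&
           halv < 15L) {
      step <- step / 2
      newTheta <- theta - step
      newDev <- devAt(newTheta)
      halv <- halv + 1L
    }
    moved <- max(abs(step))
    theta <- newTheta
    dev <- newDev
    if (moved < tol && max(abs(g)) < 1e-4) {
      converged <- TRUE
      break
    }
  }
  se <- NA_real_
  if (converged) {
    vc <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc) && vc[K, K] > 0) se <- sqrt(vc[K, K])
    else converged <- FALSE
  }
  if (abs(theta[K]) > 15) converged <- FALSE  # separation guard
  list(beta = theta[K], se = se, alpha = theta[1:(K - 1)],
       converged = converged, iter = it)
}

## logistic ML fit of y on (1, x) via Fisher scoring; returns beta, se
.fitLogistic <- function(y, x, maxit = 25L, tol = 1e-8) {
  b <- c(qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), 0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- b[1] + b[2] * x
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    g <- c(sum(y - mu), sum(x * (y - mu)))
    I11 <- sum(w); I12 <- sum(w * x); I22 <- sum(w * x^2)
    det <- I11 * I22 - I12^2
    if (!is.finite(det) || det <= 1e-12) break
    step <- c(I22 * g[1] - I12 * g[2], I11 * g[2] - I12 * g[1]) / det
    b <- b + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- NA_real_
  if (converged) {
    eta <- b[1] + b[2] * x
    w <- plogis(eta) * (1 - plogis(eta))
    I11 <- sum(w); I12 <- sum(w * x); I22 <- sum(w * x^2)
    det <- I11 * I22 - I12^2
    if (det > 1e-12) se <- sqrt(I11 / det)
  }
  if (abs(b[2]) > 15) converged <- FALSE
  list(beta = b[2], se = se, converged = converged)
}

#' Per-SNP GWAS summary statistics from a synthetic study
#'
#' Fits each SNP against each trait: proportional-odds regression for the
#' ordinal traits (NP, NFT), logistic regression for the binary trait
#' (CAA), each on the dosage (beta per effect-allele copy on the log-odds
#' scale). SNPs whose fit fails to converge (e.g. separation) are dropped
#' from that trait's table and counted in its report.
#'
#' @param study a \code{\link{SyntheticStudy}}, or a dosage matrix (then
#'   \code{phenotypes} and \code{snpMap} must be given).
#' @param phenotypes,snpMap used when \code{study} is a plain matrix.
#' @param models named character vector mapping trait to
#'   \code{"proportional_odds"} or \code{"logistic"}.
#' @return named list of \code{\link{TraitSumStats}}, one per trait.
#' @export
fitSumStats <- function(study, phenotypes = NULL, snpMap = NULL,
                        models = c(NP = "proportional_odds",
                                   NFT = "proportional_odds",
                                   CAA = "logistic")) {
  if (is(study, "SyntheticStudy")) {
    dos <- study@dosages
    phenotypes <- study@phenotypes
    snpMap <- study@snpMap
  } else {
    dos <- study
    stopifnot(!is.null(phenotypes), !is.null(snpMap))
  }
  stopifnot(all(names(models) %in% names(phenotypes)))
  M <- ncol(dos)
  mono <- apply(dos, 2, function(v) length(unique(v)) < 2L)
  if (all(mono)) stop("input error: every SNP is monomorphic")
  eaf <- colMeans(dos) / 2
  out <- list()
  for (tr in names(models)) {
    yraw <- phenotypes[[tr]]
    if (length(unique(yraw)) < 2L)
      stop("input error: trait ", tr, " is degenerate (single level)")
    beta <- se <- rep(NA_real_, M)
    if (models[[tr]] == "proportional_odds") {
      y <- as.integer(yraw) + 1L - min(as.integer(yraw))
      y <- match(y, sort(unique(y)))
      for (j in which(!mono)) {
        f <- fitPropOdds(y, dos[, j])
        if (f$converged) {
          beta[j] <- f$beta; se[j] <- f$se
        }
      }
    } else if (models[[tr]] == "logistic") {
      y <- if (is.character(yraw) || is.factor(yraw))
        as.integer(yraw %in% c("AD", "1", "present"))
      else as.integer(yraw != 0)
      for (j in which(!mono)) {
        f <- .fitLogistic(y, dos[, j])
        if (f$converged) {
          beta[j] <- f$beta; se[j] <- f$se
        }
      }
    } else stop("configuration error: unknown model ", models[[tr]],
                " for trait ", tr)
    ok <- !is.na(beta) & !is.na(se) & se > 0
    rec <- data.frame(snp_id = snpMap$snp_id,
                      chrom = as.character(snpMap$chrom),
                      pos = snpMap$pos,
                      effect_allele = snpMap$effect_allele,
                      ref_allele = snpMap$ref_allele,
                      eaf = pmin(pmax(eaf, 1e-6), 1 - 1e-6),
                      beta = beta, se = se,
                      stringsAsFactors = FALSE)[ok, , drop = FALSE]
    rownames(rec) <- NULL
    out[[tr]] <- new("TraitSumStats", traitLabel = tr, records = rec,
                     report = list(n_snps = M,
                                   n_dropped_monomorphic = sum(mono),
                                   n_dropped_nonconverged =
                                     sum(!ok) - sum(mono)))
  }
  out
}

## ---- direct Z draws ------------------------------------------------------

#' Draw an aligned Z matrix directly from its null/alternative model
#'
#' Fast path for type-I-error and power studies of the joint test: null
#' rows are multivariate normal with covariance \code{Sigma}; the first
#' \code{round(M * signalFraction)} rows additionally receive a mean shift
#' of \code{signalSize} on the traits named in \code{signalTraits}.
#'
#' @param M number of SNP rows.
#' @param Sigma K x K positive-definite covariance (dimnames give trait
#'   labels; defaults to Z1..ZK).
#' @param signalFraction fraction of rows carrying signal.
#' @param signalSize mean shift added on signal rows.
#' @param signalTraits traits receiving the shift (default: all).
#' @param seed integer seed.
#' @return a \code{\link{ZMatrix}}; signal rows are rows
#'   \code{seq_len(round(M * signalFraction))}.
#' @export
simulateZDirect <- function(M, Sigma, signalFraction = 0,
                            signalSize = 0, signalTraits = NULL, seed) {
  stopifnot(!missing(seed), signalFraction >= 0, signalFraction <= 1)
  S <- .sigmaOf(Sigma)
  K <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("input error: Sigma must be positive definite")
  labs <- colnames(S)
  if (is.null(labs)) labs <- paste0("Z", seq_len(K))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(M * K), M, K) %*% chol(S)
  nSig <- round(M * signalFraction)
  if (nSig > 0 && signalSize != 0) {
    st <- if (is.null(signalTraits)) labs else signalTraits
    z[seq_len(nSig), match(st, labs)] <-
      z[seq_len(nSig), match(st, labs)] + signalSize
  }
  colnames(z) <- labs
  info <- data.frame(snp_id = sprintf("snp%06d", seq_len(M)),
                     chrom = "1", pos = 1000L * seq_len(M),
                     stringsAsFactors = FALSE)
  new("ZMatrix", z = z, snpInfo = info, traits = labs)
}

## ---- expression studies --------------------------------------------------

#' Simulate a normalized expression study with known effects
#'
#' Generates a gene x sample normalized-expression matrix with AD/control
#' status, the covariates used by the expression models (age at death,
#' sex, RIN, batch/plate/flow cell, tissue source, PMI, pH, preservation),
#' five cell-type marker covariates, an APOE epsilon-4 dosage and one SNP
#' dosage column. Injected truth: per-gene case-vs-control shifts
#' (\code{dgeEffects}), per-gene eQTL slopes (\code{eqtlEffects}) on the
#' SNP dosage, and a cell-composition confound in which status shifts the
#' neuronal marker ENO2 and every gene loads on ENO2 with weight
#' \code{confoundStrength}.
#'
#' @param nGenes,nSamples dimensions.
#' @param adFraction fraction of AD samples.
#' @param dgeEffects named numeric, gene id -> status effect (AD minus
#'   control, expression units).
#' @param eqtlEffects named numeric, gene id -> per-allele slope.
#' @param confoundStrength loading of every gene on the status-shifted
#'   ENO2 marker (0 = no confounding).
#' @param noiseSd residual SD of expression (default 0.5).
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment}; truth recorded in
#'   \code{metadata()}.
#' @export
simulateExpression <- function(nGenes = 100, nSamples = 200,
                               adFraction = 0.5, dgeEffects = NULL,
                               eqtlEffects = NULL, confoundStrength = 0,
                               noiseSd = 0.5, seed) {
  stopifnot(!missing(seed), adFraction > 0, adFraction < 1)
  set.seed(as.integer(seed))
  genes <- sprintf("gene%04d", seq_len(nGenes))
  samples <- sprintf("s%04d", seq_len(nSamples))
  nAD <- round(nSamples * adFraction)
  status <- sample(c(rep("AD", nAD), rep("control", nSamples - nAD)))
  sAD <- as.integer(status == "AD")
  cd <- data.frame(
    status = status,
    age_at_death = round(rnorm(nSamples, 82, 7), 1),
    sex = sample(c("F", "M"), nSamples, replace = TRUE),
    rin = pmax(4, rnorm(nSamples, 7.5, 0.8)),
    batch = sample(paste0("b", 1:4), nSamples, replace = TRUE),
    flow_cell = sample(paste0("fc", 1:4), nSamples, replace = TRUE),
    plate = sample(paste0("pl", 1:4), nSamples, replace = TRUE),
    tissue_source = sample(c("bankA", "bankB"), nSamples, replace = TRUE),
    pmi = pmax(1, rnorm(nSamples, 12, 4)),
    ph = rnorm(nSamples, 6.5, 0.3),
    preservation = sample(c("frozen", "fixed"), nSamples, replace = TRUE),
    apoe_e4 = rbinom(nSamples, 2, 0.25),
    snp_dosage = rbinom(nSamples, 2, 0.3),
    row.names = samples, stringsAsFactors = FALSE)
  markers <- matrix(rnorm(nSamples * 5), nSamples, 5,
                    dimnames = list(samples, .CELL_MARKERS))
  markers[, "ENO2"] <- markers[, "ENO2"] +
    (if (confoundStrength != 0) 1.0 else 0) * sAD
  cd <- cbind(cd, as.data.frame(markers))
  base <- rnorm(nGenes, 5, 1)
  expr <- matrix(rnorm(nGenes * nSamples, sd = noiseSd), nGenes,
                 nSamples, dimnames = list(genes, samples)) + base
  expr <- expr + confoundStrength *
    matrix(markers[, "ENO2"], nGenes, nSamples, byrow = TRUE)
  if (!is.null(dgeEffects)) {
    gix <- match(names(dgeEffects), genes)
    stopifnot(!anyNA(gix))
    expr[gix, ] <- expr[gix, ] +
      outer(as.numeric(dgeEffects), sAD)
  }
  if (!is.null(eqtlEffects)) {
    gix <- match(names(eqtlEffects), genes)
    stopifnot(!anyNA(gix))
    expr[gix, ] <- expr[gix, ] +
      outer(as.numeric(eqtlEffects), cd$snp_dosage)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(truth = list(dge = dgeEffects, eqtl = eqtlEffects,
                                 confound = confoundStrength,
                                 noise_sd = noiseSd, seed = seed)))
}

## ---- whole studies -------------------------------------------------------

#' Simulate a complete multi-trait neuropathology study
#'
#' The default study conditions: LD-blocked genotypes, three correlated
#' traits (ordinal NP and NFT, binary CAA) with realized score
#' correlations targeting 0.68/0.56/0.40, about 87 percent AD cases, and a
#' sparse causal architecture: \code{nDual} SNPs affecting both NP and NFT
#' with liability effect \code{dualEffect} per trait, and \code{nSingle}
#' SNPs affecting NP alone with the same total effect
#' (\code{dualEffect * sqrt(2)}). Causal SNPs are placed in distinct LD
#' blocks among SNPs with MAF >= 0.1.
#'
#' @param n subjects (default 2000).
#' @param M SNPs (default 20000).
#' @param nDual,nSingle causal SNP counts.
#' @param dualEffect per-trait liability effect (per SD of dosage) of a
#'   dual-effect SNP.
#' @param blockSize,rhoWithin,mafRange see \code{\link{simulateGenotypes}}.
#' @param adFraction AD case fraction (default 0.87).
#' @param seed integer seed.
#' @return a \code{\link{SyntheticStudy}}.
#' @export
simulateStudy <- function(n = 2000, M = 20000, nDual = 10, nSingle = 10,
                          dualEffect = 0.18, blockSize = 50L,
                          rhoWithin = 0.8, mafRange = c(0.01, 0.5),
                          adFraction = 0.87, seed) {
  stopifnot(!missing(seed))
  gen <- simulateGenotypes(n, M, mafRange = mafRange,
                           blockSize = blockSize,
                           rhoWithin = rhoWithin, seed = seed)
  set.seed(as.integer(seed) + 1L)
  nc <- nDual + nSingle
  causal <- NULL
  if (nc > 0) {
    elig <- which(gen$snpMap$maf >= 0.1)
    pick <- integer(0)
    usedBlocks <- integer(0)
    for (j in sample(elig)) {
      b <- gen$snpMap$block[j]
      if (!b %in% usedBlocks) {
        pick <- c(pick, j)
        usedBlocks <- c(usedBlocks, b)
        if (length(pick) == nc) break
      }
    }
    if (length(pick) < nc)
      stop("input error: not enough LD blocks for ", nc, " causal SNPs")
    singleEffect <- dualEffect * sqrt(2)
    causal <- data.frame(
      snp_id = gen$snpMap$snp_id[pick],
      NP = c(rep(dualEffect, nDual), rep(singleEffect, nSingle)),
      NFT = c(rep(dualEffect, nDual), rep(0, nSingle)),
      CAA = 0,
      type = c(rep("dual", nDual), rep("single", nSingle)),
      stringsAsFactors = FALSE)
  }
  tr <- simulateTraits(gen$dosages, causalEffects = causal,
                       adFraction = adFraction,
                       seed = as.integer(seed) + 2L)
  new("SyntheticStudy", dosages = gen$dosages, snpMap = gen$snpMap,
      phenotypes = tr$phenotypes, truth = tr$truth,
      residCorr = tr$truth$residCorr, seed = as.integer(seed))
}

#' Write a synthetic study to pipeline-readable files
#'
#' Writes the SNP map, a plain dosage table, the phenotype table, a
#' minimal VCF (GT field, synthetic panel) usable as an LD reference, and
#' the ground-truth causal table, all tab-delimited text.
#'
#' @param study a \code{\link{SyntheticStudy}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(snp_map = file.path(dir, "snp_map.tsv"),
             dosages = file.path(dir, "dosages.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             panel_vcf = file.path(dir, "panel.vcf"),
             truth = file.path(dir, "truth.tsv"))
  data.table::fwrite(study@snpMap, paths["snp_map"], sep = "\t")
  dosDf <- data.frame(sample_id = sprintf("ind%05d",
                                          seq_len(nrow(study@dosages))),
                      study@dosages, check.names = FALSE)
  data.table::fwrite(dosDf, paths["dosages"], sep = "\t")
  data.table::fwrite(cbind(sample_id = dosDf$sample_id,
                           study@phenotypes),
                     paths["phenotypes"], sep = "\t")
  writeDosagesVcf(study@dosages, study@snpMap, paths["panel_vcf"])
  truth <- study@truth$causal
  if (is.null(truth)) truth <- data.frame(snp_id = character(0))
  data.table::fwrite(truth, paths["truth"], sep = "\t")
  invisible(paths)
}

#' Write integer dosages as a minimal VCF (GT field)
#'
#' Synthetic-panel export: dosage 0/1/2 becomes genotype 0/0, 0/1, 1/1 on
#' unphased calls. The ALT allele is the effect allele.
#'
#' @param dosages n x M integer dosage matrix.
#' @param snpMap matching SNP map (snp_id, chrom, pos, effect_allele,
#'   ref_allele).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDosagesVcf <- function(dosages, snpMap, path) {
  stopifnot(ncol(dosages) == nrow(snpMap))
  n <- nrow(dosages)
  samp <- sprintf("ind%05d", seq_len(n))
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pleioscan-synthetic-panel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samp),
                     collapse = "\t")), con)
  gt <- matrix(gtCode[t(dosages) + 1L], nrow = ncol(dosages))
  lines <- paste(snpMap$chrom, snpMap$pos, snpMap$snp_id,
                 snpMap$ref_allele, snpMap$effect_allele, ".", "PASS",
                 ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a dosage matrix from a plain table or a VCF
#'
#' Plain format: first column sample id, remaining columns one SNP each.
#' VCF: the DS field is used when present, otherwise GT allele counts
#' (ALT-allele dosage).
#'
#' @param path file path.
#' @param format \code{"table"} or \code{"vcf"}.
#' @return sample x SNP numeric matrix, colnames = SNP ids.
#' @export
readDosages <- function(path, format = c("table", "vcf")) {
  format <- match.arg(format)
  if (format == "table") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                            showProgress = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- as.character(dt[[1]])
    return(m)
  }
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "##")]
  hdr <- strsplit(sub("^#", "", ln[1]), "\t")[[1]]
  body <- strsplit(ln[-1], "\t")
  samp <- hdr[-(1:9)]
  ids <- vapply(body, `[`, character(1), 3L)
  fmt <- strsplit(vapply(body, `[`, character(1), 9L), ":")
  dsField <- vapply(fmt, function(f) match("DS", f), integer(1))
  gtField <- vapply(fmt, function(f) match("GT", f), integer(1))
  m <- matrix(NA_real_, length(samp), length(body),
              dimnames = list(samp, ids))
  for (i in seq_along(body)) {
    cells <- strsplit(body[[i]][-(1:9)], ":")
    if (!is.na(dsField[i])) {
      m[, i] <- as.numeric(vapply(cells, `[`, character(1), dsField[i]))
    } else if (!is.na(gtField[i])) {
      gt <- vapply(cells, `[`, character(1), gtField[i])
      m[, i] <- vapply(strsplit(gt, "[/|]"), function(a)
        sum(as.integer(a) > 0), numeric(1))
    } else stop("input error: VCF record without DS or GT: ", ids[i])
  }
  m
}
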