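#' Estimate the between-trait covariance of GWAS test statistics
#'
#' The null covariance of per-trait Z statistics is approximated by the
#' sample covariance of the Z matrix over all SNPs (default). Because the
#' overwhelming majority of genome-wide SNPs are null, this sample
#' covariance is dominated by the null distribution; a truncated mode
#' restricting to rows with every |z| below \code{zCap} is available as a
#' robustness option for signal-dense inputs. If the estimate is not
#' positive definite it is regularized by the smallest diagonal inflation
#' that makes it so.
#'
#' @param Z a \code{\link{ZMatrix}} (or plain M x K matrix).
#' @param mode \code{"all_snps"} (default) or \code{"truncated"}.
#' @param zCap absolute-Z cap for truncated mode.
#' @return a \code{\link{TestCovariance}}.
#' @export
estimateCovariance <- function(Z, mode = c("all_snps", "truncated"),
                               zCap = 2) {
  mode <- match.arg(mode)
  zm <- if (is(Z, "ZMatrix")) Z@z else as.matrix(Z)
  K <- ncol(zm)
  if (nrow(zm) <= 10 * K)
    stop("input error: need more than ", 10 * K,
         " SNP rows to estimate a ", K, "x", K, " covariance")
  if (mode == "truncated") {
    keep <- rowSums(abs(zm) < zCap) == K
    if (sum(keep) <= 10 * K)
      stop("input error: truncated mode retains too few rows (",
           sum(keep), ")")
    zm <- zm[keep, , drop = FALSE]
  }
  S <- stats::cov(zm)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floorEv <- 1e-8 * max(ev)
  if (min(ev) < floorEv) S <- S + diag(floorEv - min(ev), K)
  dimnames(S) <- list(colnames(zm), colnames(zm))
  new("TestCovariance", sigma = S, mode = mode, nSnps = nrow(zm))
}

.sigmaOf <- function(Sigma) {
  if (is(Sigma, "TestCovariance")) Sigma@sigma else as.matrix(Sigma)
}

#' O'Brien combined statistic for one SNP
#'
#' Combines a SNP's per-trait Z statistics into a single statistic that is
#' standard normal under the global null of no association with any trait.
#' The default generalized-least-squares weighting is
#' \deqn{T = \frac{1'\Sigma^{-1} z}{\sqrt{1'\Sigma^{-1} 1}},}
#' the equal weighting is \eqn{T = 1'z / \sqrt{1'\Sigma 1}}; the two
#' coincide whenever \eqn{\Sigma} is equicorrelated, and the GLS form is
#' invariant to rescaling of \eqn{\Sigma}.
#'
#' @param z numeric vector of length K (one SNP's Z per trait).
#' @param Sigma \code{\link{TestCovariance}} or K x K matrix.
#' @param weights \code{"gls"} (default) or \code{"equal"}.
#' @return the combined statistic (scalar).
#' @export
obrienStatistic <- function(z, Sigma, weights = c("gls", "equal")) {
  weights <- match.arg(weights)
  S <- .sigmaOf(Sigma)
  K <- length(z)
  stopifnot(nrow(S) == K, ncol(S) == K)
  one <- rep(1, K)
  if (weights == "gls") {
    w <- tryCatch(solve(S, one), error = function(e)
      stop("numerical error: singular covariance for trait subset {",
           paste(colnames(S), collapse = ", "), "}"))
    sum(w * z) / sqrt(sum(w))
  } else {
    sum(z) / sqrt(sum(S))
  }
}

## row-wise combined statistic for an M x K matrix of Z scores
.obrienRows <- function(zm, S, weights) {
  K <- ncol(zm)
  one <- rep(1, K)
  if (weights == "gls") {
    w <- tryCatch(solve(S, one), error = function(e)
      stop("numerical error: singular covariance for trait subset {",
           paste(colnames(S), collapse = ", "), "}"))
    drop(zm %*% w) / sqrt(sum(w))
  } else {
    rowSums(zm) / sqrt(sum(S))
  }
}

#' Classify SNPs under the pleiotropy declaration rule
#'
#' A SNP is declared pleiotropic for a trait subset when the joint p-value
#' is at least one order of magnitude more significant than every member
#' trait's univariate p-value (\code{pJoint <= pUniv / magnitudeFactor})
#' and every univariate p-value is at least nominally significant
#' (\code{pUniv < nominal}). It is genome-wide-significant pleiotropic
#' when, additionally, \code{pJoint < gws}. Comparisons are done in log10
#' space so extreme p-values classify correctly.
#'
#' @param pJoint numeric vector of joint p-values (one per SNP).
#' @param pUniv matrix (SNP x trait) or vector of univariate p-values.
#' @param gws genome-wide significance threshold (default 5e-8).
#' @param magnitudeFactor significance-magnitude factor (default 10).
#' @param nominal nominal significance level (default 0.05).
#' @param log10p set TRUE when \code{pJoint}/\code{pUniv} are already
#'   log10 p-values.
#' @return factor with levels \code{not_pleiotropic}, \code{pleiotropic},
#'   \code{gws_pleiotropic}.
#' @export
classifyPleiotropy <- function(pJoint, pUniv, gws = 5e-8,
                               magnitudeFactor = 10, nominal = 0.05,
                               log10p = FALSE) {
  if (is.null(dim(pUniv))) pUniv <- matrix(pUniv, nrow = length(pJoint))
  stopifnot(nrow(pUniv) == length(pJoint),
            gws > 0, gws < 1, nominal > 0, nominal < 1,
            magnitudeFactor > 0)
  if (!log10p) {
    if (any(pJoint <= 0 | pJoint > 1) || any(pUniv <= 0 | pUniv > 1))
      stop("input error: p-values must lie in (0, 1]")
    lj <- log10(pJoint); lu <- log10(pUniv)
  } else {
    lj <- pJoint; lu <- pUniv
  }
  magOk <- rowSums(lj <= lu - log10(magnitudeFactor)) == ncol(lu)
  nomOk <- rowSums(lu < log10(nominal)) == ncol(lu)
  pleio <- magOk & nomOk
  gwsP <- pleio & (lj < log10(gws))
  factor(ifelse(gwsP, "gws_pleiotropic",
                ifelse(pleio, "pleiotropic", "not_pleiotropic")),
         levels = c("not_pleiotropic", "pleiotropic", "gws_pleiotropic"))
}

#' Joint O'Brien scan over a trait subset
#'
#' Computes the combined statistic, its two-sided p-value and the
#' pleiotropy classification for every SNP, for a subset of 1-3 traits.
#' With a single trait the joint p equals the univariate p exactly.
#'
#' @param Z a \code{\link{ZMatrix}}.
#' @param Sigma a \code{\link{TestCovariance}} estimated from \code{Z} (its
#'   rows/columns are subset to \code{traits}); \code{NULL} estimates it
#'   from \code{Z} with the default all-SNPs mode.
#' @param traits character vector of member trait labels (length 1-3).
#' @param weights \code{"gls"} or \code{"equal"} (see
#'   \code{\link{obrienStatistic}}).
#' @param gws,magnitudeFactor,nominal passed to
#'   \code{\link{classifyPleiotropy}}.
#' @return data.frame: snp_id, chrom, pos, per-trait \code{z_}/\code{p_}
#'   columns, \code{t_joint}, \code{p_joint}, \code{log10p_joint},
#'   \code{class}.
#' @export
jointScan <- function(Z, Sigma = NULL, traits = traitLabels(Z),
                      weights = c("gls", "equal"), gws = 5e-8,
                      magnitudeFactor = 10, nominal = 0.05) {
  weights <- match.arg(weights)
  stopifnot(is(Z, "ZMatrix"))
  missing <- setdiff(traits, Z@traits)
  if (length(missing))
    stop("configuration error: trait(s) not in Z matrix: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(traits))
    stop("configuration error: duplicated trait in subset: ",
         paste(traits[duplicated(traits)], collapse = ", "))
  if (is.null(Sigma)) Sigma <- estimateCovariance(Z)
  S <- .sigmaOf(Sigma)
  if (is.null(colnames(S))) {
    if (nrow(S) == length(Z@traits)) dimnames(S) <- list(Z@traits, Z@traits)
    else if (nrow(S) != length(traits))
      stop("configuration error: Sigma dimension matches neither Z nor ",
           "the trait subset")
    else dimnames(S) <- list(traits, traits)
  }
  S <- S[traits, traits, drop = FALSE]
  zm <- Z@z[, traits, drop = FALSE]
  ## K = 1: the joint statistic reduces to the univariate Z itself, so the
  ## joint p equals the univariate p exactly
  tj <- if (length(traits) == 1L) zm[, 1L] else .obrienRows(zm, S, weights)
  ljoint <- log10TwoSidedP(tj)
  luniv <- matrix(log10TwoSidedP(zm), ncol = length(traits))
  out <- Z@snpInfo[, c("snp_id", "chrom", "pos")]
  for (k in seq_along(traits)) {
    out[[paste0("z_", traits[k])]] <- zm[, k]
    out[[paste0("p_", traits[k])]] <- 10^luniv[, k]
  }
  out$t_joint <- tj
  out$p_joint <- 10^ljoint
  out$log10p_joint <- ljoint
  out$class <- classifyPleiotropy(ljoint, luniv, gws = gws,
                                  magnitudeFactor = magnitudeFactor,
                                  nominal = nominal, log10p = TRUE)
  rownames(out) <- NULL
  out
}

.CHI1_MEDIAN <- qchisq(0.5, df = 1)

#' Genomic-control lambda
#'
#' Ratio of the median association chi-square (1 df, from the p-values) to
#' the null chi-square median (about 0.4549); lambda near 1 indicates no
#' genome-wide inflation. An optional region (e.g. the APOE locus,
#' defaulting coordinates \code{chr19:44.4-46.5 Mb} when requested by the
#' caller) can be excluded before the median is taken.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param excludeRegion optional \code{list(chrom=, start=, end=)};
#'   requires \code{chrom}/\code{pos}.
#' @param chrom,pos per-SNP coordinates, only needed with
#'   \code{excludeRegion}.
#' @return lambda (scalar).
#' @export
genomicLambda <- function(p, excludeRegion = NULL, chrom = NULL,
                          pos = NULL) {
  if (length(p) == 0L) stop("input error: empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("input error: p-values must lie in (0, 1]")
  if (!is.null(excludeRegion)) {
    stopifnot(!is.null(chrom), !is.null(pos))
    drop <- chrom == as.character(excludeRegion$chrom) &
      pos >= excludeRegion$start & pos <= excludeRegion$end
    p <- p[!drop]
    if (length(p) == 0L)
      stop("input error: exclusion region removed every SNP")
  }
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / .CHI1_MEDIAN
}

#' APOE-region coordinates used for lambda sensitivity checks
#'
#' GRCh37 window chr19:44.4-46.5 Mb containing the APOE locus.
#' @export
apoeRegion <- function() list(chrom = "19", start = 44.4e6, end = 46.5e6)

#' Observed-vs-expected quantile table for a QQ plot
#'
#' Observed p-values sorted ascending against uniform expected quantiles
#' \code{rank/(n+1)}, both returned as -log10.
#'
#' @param p numeric vector of p-values (duplicates allowed).
#' @return data.frame with columns \code{expected}, \code{observed}
#'   (-log10 scale), both nondecreasing down the table.
#' @export
qqTable <- function(p) {
  if (length(p) == 0L) stop("input error: empty p-value vector")
  n <- length(p)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(p, decreasing = FALSE)))
}
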