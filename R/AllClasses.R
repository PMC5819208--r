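#' @import methods
#' @importFrom stats pnorm qnorm dnorm plogis qlogis pchisq qchisq median cor
#'   cov sd
#'   rnorm rbinom runif rlogis complete.cases lm model.matrix pt qlogis
#'   integrate uniroot setNames coef vcov quantile ks.test var
#' @importFrom utils head
NULL

#' Per-trait GWAS summary statistics
#'
#' Container for one trait's per-SNP association results: effect sizes
#' (log-odds scale for the ordinal/binary trait models used here), standard
#' errors, allele coding and frequency, plus optional imputation-quality
#' fields used by QC.
#'
#' @slot traitLabel single character, e.g. \code{"NP"}.
#' @slot records data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based), \code{effect_allele}, \code{ref_allele},
#'   \code{eaf}, \code{beta}, \code{se}, and optionally \code{imput_r2},
#'   \code{dosage_var}.
#' @slot report list of counts accumulated by \code{\link{readSumStats}} and
#'   \code{\link{qcFilter}}.
#'
#' @export
setClass("TraitSumStats",
  representation(traitLabel = "character", records = "data.frame",
                 report = "list"),
  prototype(traitLabel = NA_character_,
            records = data.frame(), report = list()))

setValidity("TraitSumStats", function(object) {
  msgs <- character(0)
  rec <- object@records
  if (length(object@traitLabel) != 1L)
    msgs <- c(msgs, "traitLabel must be a single string")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "ref_allele",
            "eaf", "beta", "se")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    msgs <- c(msgs, paste0("records lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(rec)) {
    if (anyDuplicated(rec$snp_id))
      msgs <- c(msgs, "snp_id values must be unique")
    if (any(!is.finite(rec$se) | rec$se <= 0))
      msgs <- c(msgs, "all se must be finite and > 0")
    if (any(!is.finite(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1))
      msgs <- c(msgs, "all eaf must lie strictly inside (0, 1)")
    bad <- !(rec$effect_allele %in% c("A", "C", "G", "T")) |
      !(rec$ref_allele %in% c("A", "C", "G", "T"))
    if (any(bad))
      msgs <- c(msgs, "alleles must be one of A/C/G/T")
  }
  if (length(msgs)) msgs else TRUE
})

#' Multi-trait summary statistics aligned on one shared SNP set
#'
#' Every SNP is present in all traits, with a single effect-allele
#' orientation shared across traits; \code{z = beta / se} per entry.
#'
#' @slot snpInfo data.frame with \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{ref_allele} (one row per SNP).
#' @slot traits character vector of trait labels (column order of the
#'   matrices).
#' @slot beta,se,z M x K matrices.
#' @slot log10p M x K matrix of log10 two-sided normal p-values (kept in log
#'   space so extreme statistics never underflow).
#' @slot report list of harmonization counts.
#'
#' @export
setClass("AlignedSumStats",
  representation(snpInfo = "data.frame", traits = "character",
                 beta = "matrix", se = "matrix", z = "matrix",
                 log10p = "matrix", report = "list"))

setValidity("AlignedSumStats", function(object) {
  msgs <- character(0)
  M <- nrow(object@snpInfo); K <- length(object@traits)
  for (nm in c("beta", "se", "z", "log10p")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(M, K)))
      msgs <- c(msgs, paste0(nm, " must be ", M, " x ", K))
  }
  if (!length(msgs) && M > 0) {
    rel <- abs(object@z * object@se - object@beta) /
      pmax(abs(object@beta), 1)
    if (any(rel > 1e-12))
      msgs <- c(msgs, "z must equal beta/se to 1e-12 relative error")
  }
  if (length(msgs)) msgs else TRUE
})

#' Aligned matrix of signed Z statistics
#'
#' @slot z M x K numeric matrix of signed Z statistics, no missing entries.
#' @slot snpInfo data.frame with \code{snp_id}, \code{chrom}, \code{pos}.
#' @slot traits character vector of K trait labels.
#'
#' @export
setClass("ZMatrix",
  representation(z = "matrix", snpInfo = "data.frame", traits = "character"))

setValidity("ZMatrix", function(object) {
  msgs <- character(0)
  if (anyNA(object@z)) msgs <- c(msgs, "z must have no missing entries")
  if (ncol(object@z) != length(object@traits))
    msgs <- c(msgs, "ncol(z) must equal length(traits)")
  if (nrow(object@z) != nrow(object@snpInfo))
    msgs <- c(msgs, "nrow(z) must equal nrow(snpInfo)")
  if (nrow(object@z) < ncol(object@z))
    msgs <- c(msgs, "need at least as many SNPs as traits")
  if (length(msgs)) msgs else TRUE
})

#' Between-trait covariance of GWAS test statistics
#'
#' The null covariance of the per-trait Z statistics, approximated by the
#' sample covariance of the Z matrix over all (or truncated) SNPs.
#'
#' @slot sigma K x K symmetric positive-definite matrix.
#' @slot mode estimation mode, \code{"all_snps"} or \code{"truncated"}.
#' @slot nSnps number of SNP rows used.
#'
#' @export
setClass("TestCovariance",
  representation(sigma = "matrix", mode = "character", nSnps = "integer"))

setValidity("TestCovariance", function(object) {
  msgs <- character(0)
  S <- object@sigma
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "sigma must be square")
  else {
    if (max(abs(S - t(S))) > 1e-12)
      msgs <- c(msgs, "sigma must be symmetric to 1e-12")
    if (any(diag(S) <= 0))
      msgs <- c(msgs, "sigma diagonal must be positive")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msgs <- c(msgs, "sigma must be positive definite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Linkage-disequilibrium correlation matrix for one gene window
#'
#' Pearson correlation of reference-panel dosages, shrunk toward the
#' identity just enough to be numerically positive semi-definite.
#'
#' @slot R S x S correlation matrix (unit diagonal).
#' @slot snpIds SNP identifiers, one per row/column of \code{R}.
#' @slot shrinkage shrinkage intensity applied (0 = none).
#'
#' @export
setClass("LDMatrix",
  representation(R = "matrix", snpIds = "character", shrinkage = "numeric"))

setValidity("LDMatrix", function(object) {
  msgs <- character(0)
  R <- object@R
  if (nrow(R) != ncol(R) || nrow(R) != length(object@snpIds))
    msgs <- c(msgs, "R must be square with one snpId per row")
  else {
    if (max(abs(diag(R) - 1)) > 1e-8)
      msgs <- c(msgs, "R must have unit diagonal")
    if (max(abs(R)) > 1 + 1e-8)
      msgs <- c(msgs, "|R| entries must be <= 1")
    if (max(abs(R - t(R))) > 1e-10)
      msgs <- c(msgs, "R must be symmetric")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      msgs <- c(msgs, "R must be positive semi-definite after shrinkage")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic multi-trait neuropathology study with recorded ground truth
#'
#' LD-blocked genotype dosages, two correlated 4-level ordinal traits
#' (NP by CERAD score, NFT by Braak stage), one binary trait (CAA), an
#' AD/control status column, and the causal architecture that generated
#' them.
#'
#' @slot dosages n x M dosage matrix (0..2 scale), SNP ids as colnames.
#' @slot snpMap data.frame: \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{ref_allele}, \code{maf}, \code{block}.
#' @slot phenotypes data.frame: \code{NP} (0-3), \code{NFT} (0-3),
#'   \code{CAA} (0/1), \code{status} ("AD"/"control").
#' @slot truth list with \code{causal} (data.frame snp_id x trait effects on
#'   the liability scale) and the latent \code{residCorr} used.
#' @slot residCorr 3 x 3 latent residual correlation matrix.
#' @slot seed integer seed the study was generated from.
#'
#' @export
setClass("SyntheticStudy",
  representation(dosages = "matrix", snpMap = "data.frame",
                 phenotypes = "data.frame", truth = "list",
                 residCorr = "matrix", seed = "integer"))

setValidity("SyntheticStudy", function(object) {
  msgs <- character(0)
  if (nrow(object@snpMap) != ncol(object@dosages))
    msgs <- c(msgs, "snpMap rows must match dosage columns")
  if (nrow(object@phenotypes) != nrow(object@dosages))
    msgs <- c(msgs, "phenotype rows must match dosage rows")
  ph <- object@phenotypes
  if (nrow(ph)) {
    if (!all(ph$NP %in% 0:3) || !all(ph$NFT %in% 0:3))
      msgs <- c(msgs, "ordinal traits must take levels {0,1,2,3}")
    if (!all(ph$CAA %in% 0:1))
      msgs <- c(msgs, "CAA must be binary 0/1")
    d <- range(object@dosages)
    if (d[1] < 0 || d[2] > 2)
      msgs <- c(msgs, "dosages must lie in [0, 2]")
  }
  if (length(msgs)) msgs else TRUE
})
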