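.SUMSTATS_MANDATORY <- c("snp_id", "chrom", "pos", "effect_allele",
                         "ref_allele", "eaf", "beta", "se")
.SUMSTATS_OPTIONAL <- c("p", "imput_r2", "dosage_var")

#' Read one trait's GWAS summary statistics
#'
#' Parses a tab- or comma-delimited file (gzip transparently supported)
#' using a declarative column map. Rows whose mapped numeric fields do not
#' parse are dropped and counted in the load report. Any p-value column in
#' the file is ignored: p-values are always recomputed from beta/se so the
#' univariate and joint tests share one convention.
#'
#' @param path file path.
#' @param columnMap named character vector mapping field names
#'   (\code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{ref_allele}, \code{eaf}, \code{beta}, \code{se}, optionally
#'   \code{imput_r2}, \code{dosage_var}) to column names in the file.
#'   Fields whose mapped name equals the field name may be omitted.
#' @param traitLabel label for the trait, e.g. \code{"NFT"}.
#' @return a \code{\link{TraitSumStats}}; \code{qcReport(x)$n_dropped_parse}
#'   counts dropped rows.
#' @export
readSumStats <- function(path, columnMap = NULL, traitLabel = "trait") {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L) stop("input error: empty summary-statistics file: ",
                           path)
  cmap <- setNames(.SUMSTATS_MANDATORY, .SUMSTATS_MANDATORY)
  cmap <- c(cmap, setNames(.SUMSTATS_OPTIONAL, .SUMSTATS_OPTIONAL))
  if (!is.null(columnMap)) cmap[names(columnMap)] <- columnMap
  for (f in .SUMSTATS_MANDATORY) {
    if (!cmap[[f]] %in% names(dt))
      stop("configuration error: mapped column for ", sQuote(f),
           " (", sQuote(cmap[[f]]), ") not present in ", path)
  }
  rec <- data.frame(
    snp_id = dt[[cmap[["snp_id"]]]],
    chrom = sub("^chr", "", dt[[cmap[["chrom"]]]]),
    pos = suppressWarnings(as.integer(dt[[cmap[["pos"]]]])),
    effect_allele = toupper(dt[[cmap[["effect_allele"]]]]),
    ref_allele = toupper(dt[[cmap[["ref_allele"]]]]),
    eaf = suppressWarnings(as.numeric(dt[[cmap[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(dt[[cmap[["beta"]]]])),
    se = suppressWarnings(as.numeric(dt[[cmap[["se"]]]])),
    stringsAsFactors = FALSE)
  for (f in c("imput_r2", "dosage_var")) {
    if (cmap[[f]] %in% names(dt))
      rec[[f]] <- suppressWarnings(as.numeric(dt[[cmap[[f]]]]))
  }
  num <- c("pos", "eaf", "beta", "se")
  ok <- Reduce(`&`, lapply(rec[num], is.finite))
  ok <- ok & rec$se > 0 & rec$eaf > 0 & rec$eaf < 1 &
    rec$effect_allele %in% c("A", "C", "G", "T") &
    rec$ref_allele %in% c("A", "C", "G", "T")
  dup <- duplicated(rec$snp_id)
  report <- list(n_read = nrow(rec),
                 n_dropped_parse = sum(!ok),
                 n_dropped_duplicate_id = sum(dup & ok))
  rec <- rec[ok & !dup, , drop = FALSE]
  rownames(rec) <- NULL
  new("TraitSumStats", traitLabel = traitLabel, records = rec,
      report = report)
}

#' Write summary statistics in the format \code{readSumStats} reads
#'
#' Numeric fields are written with 15 significant digits so a write/read
#' round trip preserves them to at least 12 significant digits.
#'
#' @param x a \code{TraitSumStats}.
#' @param path output path (\code{.gz} suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeSumStats <- function(x, path) {
  stopifnot(is(x, "TraitSumStats"))
  rec <- x@records
  num <- vapply(rec, is.double, logical(1))
  rec[num] <- lapply(rec[num], function(v) sprintf("%.15g", v))
  data.table::fwrite(rec, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' QC-filter summary statistics on MAF, imputation quality and dosage
#' variance
#'
#' A SNP is excluded when its minor allele frequency is \code{<=}
#' \code{mafMaxExcl}, its imputation R-squared is \code{<=}
#' \code{r2MinExcl}, or its dosage variance is \code{<=}
#' \code{dosvarMinExcl}; all boundaries are inclusive exclusions. MAF is
#' \code{min(eaf, 1 - eaf)}. A missing optional field passes that
#' criterion (those filters are assumed applied upstream when the column is
#' absent). Filtering never fails; per-rule exclusion counts are recorded
#' in the report.
#'
#' @param x a \code{TraitSumStats}.
#' @param mafMaxExcl,r2MinExcl,dosvarMinExcl exclusion thresholds.
#' @return the filtered \code{TraitSumStats}; see \code{qcReport()}.
#' @export
qcFilter <- function(x, mafMaxExcl = 0.01, r2MinExcl = 0.4,
                     dosvarMinExcl = 0.02) {
  stopifnot(is(x, "TraitSumStats"),
            mafMaxExcl > 0, mafMaxExcl < 0.5,
            r2MinExcl >= 0, r2MinExcl < 1, dosvarMinExcl >= 0)
  rec <- x@records
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  exMaf <- maf <= mafMaxExcl
  exR2 <- if ("imput_r2" %in% names(rec))
    !is.na(rec$imput_r2) & rec$imput_r2 <= r2MinExcl else rep(FALSE, nrow(rec))
  exDv <- if ("dosage_var" %in% names(rec))
    !is.na(rec$dosage_var) & rec$dosage_var <= dosvarMinExcl
  else rep(FALSE, nrow(rec))
  drop <- exMaf | exR2 | exDv
  rep2 <- c(x@report, list(
    qc_n_in = nrow(rec),
    qc_excluded_maf = sum(exMaf),
    qc_excluded_imput_r2 = sum(exR2),
    qc_excluded_dosage_var = sum(exDv),
    qc_n_retained = sum(!drop)))
  out <- rec[!drop, , drop = FALSE]
  rownames(out) <- NULL
  new("TraitSumStats", traitLabel = x@traitLabel, records = out,
      report = rep2)
}

## strand-ambiguous allele pairs cannot be disambiguated without strand info
.isAmbiguous <- function(ea, ra) {
  (ea == "A" & ra == "T") | (ea == "T" & ra == "A") |
    (ea == "C" & ra == "G") | (ea == "G" & ra == "C")
}

#' Harmonize several traits onto one shared, consistently oriented SNP set
#'
#' SNPs are keyed by (chromosome, position); the SNP set is the
#' intersection across traits. The first trait fixes the effect-allele
#' orientation: a trait whose (effect, ref) pair is swapped relative to it
#' has its beta sign flipped and eaf complemented; a SNP whose allele pair
#' cannot be reconciled in any trait is dropped and counted. Duplicated
#' positions within a trait are dropped with a report (the behaviour for
#' multi-allelic sites). Strand-ambiguous A/T and C/G SNPs are kept and
#' matched by allele letters alone unless \code{dropAmbiguous = TRUE}.
#'
#' @param traits list of \code{TraitSumStats} (length >= 1).
#' @param dropAmbiguous drop strand-ambiguous SNPs instead of keeping them.
#' @return an \code{\link{AlignedSumStats}} with per-trait beta/se/z and
#'   log10 p matrices.
#' @export
harmonizeTraits <- function(traits, dropAmbiguous = FALSE) {
  stopifnot(is.list(traits), length(traits) >= 1,
            all(vapply(traits, is, logical(1), "TraitSumStats")))
  labs <- vapply(traits, traitLabel, character(1))
  if (anyDuplicated(labs))
    stop("configuration error: duplicated trait labels: ",
         paste(labs[duplicated(labs)], collapse = ", "))
  recs <- lapply(traits, records)
  nDupPos <- 0L
  for (i in seq_along(recs)) {
    key <- paste(recs[[i]]$chrom, recs[[i]]$pos)
    dup <- key %in% key[duplicated(key)]
    nDupPos <- nDupPos + sum(dup)
    recs[[i]] <- recs[[i]][!dup, , drop = FALSE]
    rownames(recs[[i]]) <- paste(recs[[i]]$chrom, recs[[i]]$pos)
  }
  shared <- Reduce(intersect, lapply(recs, rownames))
  if (length(shared) == 0L)
    stop("input error: no SNPs shared across all traits")
  recs <- lapply(recs, function(r) r[shared, , drop = FALSE])
  anchor <- recs[[1L]]
  nAmb <- sum(.isAmbiguous(anchor$effect_allele, anchor$ref_allele))
  keep <- rep(TRUE, length(shared))
  if (dropAmbiguous)
    keep <- keep & !.isAmbiguous(anchor$effect_allele, anchor$ref_allele)
  nIrrec <- 0L
  for (i in seq_along(recs)[-1L]) {
    r <- recs[[i]]
    same <- r$effect_allele == anchor$effect_allele &
      r$ref_allele == anchor$ref_allele
    swap <- r$effect_allele == anchor$ref_allele &
      r$ref_allele == anchor$effect_allele & !same
    r$beta[swap] <- -r$beta[swap]
    r$eaf[swap] <- 1 - r$eaf[swap]
    r$effect_allele[swap] <- anchor$effect_allele[swap]
    r$ref_allele[swap] <- anchor$ref_allele[swap]
    bad <- !(same | swap)
    nIrrec <- nIrrec + sum(bad & keep)
    keep <- keep & !bad
    recs[[i]] <- r
  }
  recs <- lapply(recs, function(r) r[keep, , drop = FALSE])
  anchor <- recs[[1L]]
  M <- nrow(anchor)
  if (M == 0L) stop("input error: no reconcilable SNPs shared across traits")
  beta <- vapply(recs, function(r) r$beta, numeric(M))
  se <- vapply(recs, function(r) r$se, numeric(M))
  dim(beta) <- dim(se) <- c(M, length(recs))
  z <- beta / se
  colnames(beta) <- colnames(se) <- colnames(z) <- labs
  info <- anchor[, c("snp_id", "chrom", "pos", "effect_allele",
                     "ref_allele")]
  rownames(info) <- NULL
  lp <- matrix(log10TwoSidedP(z), nrow = M, dimnames = dimnames(z))
  new("AlignedSumStats", snpInfo = info, traits = labs, beta = beta,
      se = se, z = z, log10p = lp,
      report = list(n_shared = length(shared),
                    n_dropped_duplicate_pos = nDupPos,
                    n_dropped_irreconcilable = nIrrec,
                    n_strand_ambiguous = nAmb,
                    n_aligned = M))
}

#' Log10 of the two-sided standard-normal p-value
#'
#' Computed through \code{pnorm(..., log.p = TRUE)} so it stays finite for
#' arbitrarily large statistics (|z| = 40 gives about -349.4) where the
#' natural-scale p underflows double precision.
#'
#' @param z numeric vector of Z statistics.
#' @return numeric vector of log10 p-values.
#' @export
log10TwoSidedP <- function(z) {
  (pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
}

#' Z statistic and two-sided p-value from beta and SE
#'
#' \code{z = beta / se}; the p-value is the two-sided standard-normal tail
#' probability, computed in log space so extreme statistics do not
#' underflow before the log10 column is formed.
#'
#' @param beta,se numeric vectors (recycled); all \code{se} must be > 0.
#' @return data.frame with columns \code{z}, \code{p}, \code{log10p}.
#' @export
zAndP <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0))
    stop("input error: all se must be finite and > 0")
  z <- beta / se
  lp <- log10TwoSidedP(z)
  data.frame(z = z, p = 10^lp, log10p = lp)
}

#' Write an aligned multi-trait table as tab-delimited text
#'
#' Columns: snp_id, chrom, pos, ea, ra, then per-trait beta/se/z/p.
#'
#' @param x an \code{AlignedSumStats}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAligned <- function(x, path) {
  stopifnot(is(x, "AlignedSumStats"))
  out <- x@snpInfo
  names(out)[4:5] <- c("ea", "ra")
  for (k in seq_along(x@traits)) {
    tl <- x@traits[k]
    out[[paste0("beta_", tl)]] <- x@beta[, k]
    out[[paste0("se_", tl)]] <- x@se[, k]
    out[[paste0("z_", tl)]] <- x@z[, k]
    out[[paste0("p_", tl)]] <- 10^x@log10p[, k]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
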