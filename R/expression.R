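.CELL_MARKERS <- c("ENO2", "GFAP", "CD68", "OLIG2", "CD34")

#' Named covariate presets for the expression models
#'
#' \code{"mayo_rnaseq"}: age at death, sex, RIN, brain tissue source and
#' flow cell (RNA-Seq differential expression). \code{"geo_microarray"}:
#' RIN, postmortem interval, batch, preservation method, tissue pH, age
#' and sex (microarray differential expression). \code{"mayo_eqtl"}: AD
#' status, APOE epsilon-4 dosage, age at death, sex, plate, RIN and
#' adjusted RIN (cis-eQTL models). Cell-type marker expression (ENO2,
#' GFAP, CD68, OLIG2, CD34) is appended to the DGE presets when
#' \code{markers = TRUE}.
#'
#' @param name preset name.
#' @param markers include the five CNS cell-type marker covariates.
#' @return character vector of covariate column names.
#' @export
covariatePreset <- function(name = c("mayo_rnaseq", "geo_microarray",
                                     "mayo_eqtl"), markers = TRUE) {
  name <- match.arg(name)
  base <- switch(name,
    mayo_rnaseq = c("age_at_death", "sex", "rin", "tissue_source",
                    "flow_cell"),
    geo_microarray = c("rin", "pmi", "batch", "preservation", "ph",
                       "age_at_death", "sex"),
    mayo_eqtl = c("status", "apoe_e4", "age_at_death", "sex", "plate",
                  "rin", "rin_adj"))
  if (markers && name != "mayo_eqtl") c(base, .CELL_MARKERS) else base
}

## adjusted-RIN term; the printed "RIN - RINmean^2" formula is ambiguous,
## default is the centered quadratic (RIN - mean(RIN))^2
.adjustedRin <- function(rin, form = c("centered_sq", "verbatim")) {
  form <- match.arg(form)
  if (form == "centered_sq") (rin - mean(rin))^2 else rin - mean(rin)^2
}

.covariateFrame <- function(study, covariates, adjRinForm = "centered_sq") {
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  if ("rin_adj" %in% covariates && !"rin_adj" %in% names(cd)) {
    if (!"rin" %in% names(cd))
      stop("configuration error: covariate 'rin_adj' needs a 'rin' column")
    cd$rin_adj <- .adjustedRin(cd$rin, adjRinForm)
  }
  miss <- setdiff(covariates, names(cd))
  if (length(miss))
    stop("configuration error: covariate column(s) absent: ",
         paste(miss, collapse = ", "))
  cd[, covariates, drop = FALSE]
}

## OLS of y on a focal term plus covariates with listwise deletion;
## returns the focal term's estimate
.olsTerm <- function(y, focal, df, focalName) {
  dat <- data.frame(.y = y, .focal = focal, df, check.names = TRUE)
  keep <- complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  ## drop single-level categoricals after deletion
  for (nm in names(dat)) {
    if ((is.character(dat[[nm]]) || is.factor(dat[[nm]])) &&
        length(unique(dat[[nm]])) < 2L)
      dat[[nm]] <- NULL
  }
  if (!".focal" %in% names(dat))
    stop("input error: focal predictor is constant after listwise deletion")
  n <- nrow(dat)
  fit <- lm(.y ~ ., data = dat)
  if (n - fit$rank < 10)
    stop("input error: fewer than 10 residual degrees of freedom (n_used=",
         n, ", rank=", fit$rank, ")")
  als <- is.na(coef(fit))
  if (any(als))
    stop("input error: rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[als], collapse = ", "))
  sm <- summary(fit)$coefficients
  row <- grep("^\\.focal", rownames(sm))[1]
  if (is.na(row)) stop("internal error: focal term missing from fit")
  data.frame(beta = sm[row, 1], se = sm[row, 2], p = sm[row, 4],
             n_used = n)
}

#' Differential-expression linear model for one gene
#'
#' Ordinary least squares of (already normalized) expression on AD status
#' plus a named covariate set. A negative beta means lower expression in
#' AD cases than controls. The p-value is the two-sided t-test for the
#' status term.
#'
#' @param study a \code{SummarizedExperiment}: assay is a gene x sample
#'   normalized expression matrix; \code{colData} holds the covariates
#'   (including a \code{status} column coded \code{"AD"}/\code{"control"})
#'   and the five cell-marker expression columns.
#' @param gene gene (row) identifier.
#' @param covariates a preset name (see \code{\link{covariatePreset}}) or
#'   an explicit character vector of colData columns.
#' @param markers include cell-type marker covariates (preset case only).
#' @return one-row data.frame: \code{gene_id}, \code{beta}, \code{se},
#'   \code{p}, \code{n_used}.
#' @export
dgeLm <- function(study, gene, covariates = "mayo_rnaseq",
                  markers = TRUE) {
  stopifnot(is(study, "SummarizedExperiment"))
  expr <- SummarizedExperiment::assay(study)
  if (!gene %in% rownames(expr))
    stop("configuration error: gene not in expression matrix: ", gene)
  covs <- if (length(covariates) == 1L &&
              covariates %in% c("mayo_rnaseq", "geo_microarray"))
    covariatePreset(covariates, markers = markers) else covariates
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  if (!"status" %in% names(cd))
    stop("configuration error: colData lacks 'status'")
  status <- as.integer(cd$status == "AD")
  df <- .covariateFrame(study, setdiff(covs, "status"))
  res <- .olsTerm(as.numeric(expr[gene, ]), status, df, "status")
  cbind(data.frame(gene_id = gene, stringsAsFactors = FALSE), res)
}

#' cis-eQTL linear model for one gene and one SNP
#'
#' Ordinary least squares of expression on the SNP dosage (per effect-
#' allele copy) plus the eQTL covariate set; within an AD or control
#' stratum the status covariate is omitted.
#'
#' @param study a \code{SummarizedExperiment} (see \code{\link{dgeLm}}).
#' @param gene gene (row) identifier.
#' @param snpDosage numeric per-sample dosage in [0, 2], or the name of a
#'   colData column holding it.
#' @param stratum \code{"all"}, \code{"AD"} or \code{"control"}.
#' @param covariates preset name or explicit covariate vector (default
#'   \code{"mayo_eqtl"}).
#' @param adjRinForm \code{"centered_sq"} (default) or \code{"verbatim"}
#'   form of the adjusted-RIN covariate.
#' @return one-row data.frame: \code{gene_id}, \code{beta}, \code{se},
#'   \code{p}, \code{n_used}.
#' @export
eqtlLm <- function(study, gene, snpDosage, stratum = c("all", "AD",
                                                       "control"),
                   covariates = "mayo_eqtl", adjRinForm = "centered_sq") {
  stratum <- match.arg(stratum)
  stopifnot(is(study, "SummarizedExperiment"))
  expr <- SummarizedExperiment::assay(study)
  if (!gene %in% rownames(expr))
    stop("configuration error: gene not in expression matrix: ", gene)
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  if (is.character(snpDosage) && length(snpDosage) == 1L) {
    if (!snpDosage %in% names(cd))
      stop("configuration error: dosage column absent: ", snpDosage)
    snpDosage <- cd[[snpDosage]]
  }
  if (any(snpDosage < 0 | snpDosage > 2, na.rm = TRUE))
    stop("input error: dosages must lie in [0, 2]")
  covs <- if (identical(covariates, "mayo_eqtl"))
    covariatePreset("mayo_eqtl") else covariates
  keep <- rep(TRUE, ncol(expr))
  if (stratum != "all") {
    keep <- cd$status == stratum | (stratum == "control" &
                                      cd$status != "AD")
    if (stratum == "AD") keep <- cd$status == "AD"
    if (!any(keep)) stop("input error: stratum ", sQuote(stratum),
                         " contains no samples")
    covs <- setdiff(covs, "status")
  }
  dos <- snpDosage[keep]
  if (length(unique(dos[!is.na(dos)])) < 2L)
    stop("input error: monomorphic dosage in stratum ", sQuote(stratum))
  sub <- study[, keep]
  cds <- as.data.frame(SummarizedExperiment::colData(sub))
  df <- .covariateFrame(sub, setdiff(covs, "status"), adjRinForm)
  if ("status" %in% covs)
    df$status <- as.integer(cds$status == "AD")
  res <- .olsTerm(as.numeric(SummarizedExperiment::assay(sub)[gene, ]),
                  dos, df, "dosage")
  cbind(data.frame(gene_id = gene, stringsAsFactors = FALSE), res)
}

#' Bonferroni correction across a set of expression results
#'
#' Flags each result significant when \code{p < alpha / n}.
#'
#' @param results data.frame with a \code{p} column (e.g. rows from
#'   \code{\link{dgeLm}}).
#' @param alpha family-wise error rate (default 0.05).
#' @return \code{results} with a logical \code{significant} column; the
#'   threshold is attached as attribute \code{"threshold"}.
#' @export
correctMultiple <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) >= 1,
            "p" %in% names(results))
  th <- bonferroniThreshold(alpha, nrow(results))
  results$significant <- results$p < as.numeric(th)
  structure(results, threshold = as.numeric(th))
}
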