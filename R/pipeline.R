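#' Default run configuration
#'
#' Returns the declarative configuration list \code{\link{runPipeline}}
#' consumes. Paths must be filled in by the caller; everything else has
#' working defaults. Thresholds: genome-wide significance \code{gws},
#' nominal level \code{nominal}, significance-magnitude factor
#' \code{factor}; gene-test settings: window (bp), simulation stages and
#' seed.
#'
#' @param outDir output directory.
#' @return named list (a RunConfig).
#' @export
defaultConfig <- function(outDir = tempfile("pleioscan_run_")) {
  list(
    sumstats = list(),          # trait label -> list(path=, column_map=)
    traits = NULL,              # scan subsets; NULL = all pairs + full set
    gws = 5e-8,
    nominal = 0.05,
    factor = 10,
    weights = "gls",
    qc = list(maf_max_excl = 0.01, r2_min_excl = 0.4,
              dosvar_min_excl = 0.02),
    gene_test = list(enabled = FALSE, genes = NULL, ref = NULL,
                     ref_format = "table", window = 30000,
                     stages = c(1e3, 1e4, 1e6), seed = NULL,
                     p_column = "p_joint"),
    expression = list(enabled = FALSE),
    out_dir = outDir)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields missing from the file take the
#'   \code{\link{defaultConfig}} values.
#' @return RunConfig list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultConfig()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]) &&
        nm %in% c("qc", "gene_test", "expression"))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' Validate a run configuration
#'
#' @param config RunConfig list.
#' @return character vector of violations, each naming the field and the
#'   constraint; length zero when the configuration is valid.
#' @export
validateConfig <- function(config) {
  v <- character(0)
  chk01 <- function(name) {
    val <- config[[name]]
    if (!is.numeric(val) || length(val) != 1 || val <= 0 || val >= 1)
      paste0(name, " must be in (0,1)") else character(0)
  }
  v <- c(v, chk01("gws"), chk01("nominal"))
  if (!is.numeric(config$factor) || config$factor <= 0)
    v <- c(v, "factor must be > 0")
  if (!config$weights %in% c("gls", "equal"))
    v <- c(v, "weights must be 'gls' or 'equal'")
  if (length(config$sumstats) < 1)
    v <- c(v, "sumstats must list at least one trait")
  labs <- names(config$sumstats)
  if (!is.null(config$traits)) {
    for (sub in config$traits) {
      if (anyDuplicated(sub))
        v <- c(v, paste0("traits subset {", paste(sub, collapse = ","),
                         "} must not repeat a trait"))
      miss <- setdiff(sub, labs)
      if (length(miss))
        v <- c(v, paste0("traits subset names unknown trait(s): ",
                         paste(miss, collapse = ",")))
      if (length(sub) < 1 || length(sub) > 3)
        v <- c(v, "traits subsets must have size 1-3")
    }
  }
  if (isTRUE(config$gene_test$enabled)) {
    if (is.null(config$gene_test$seed))
      v <- c(v, "gene_test.seed is required when gene tests are enabled")
    if (is.null(config$gene_test$genes))
      v <- c(v, "gene_test.genes path is required")
    if (is.null(config$gene_test$ref))
      v <- c(v, "gene_test.ref path is required")
  }
  v
}

.stageLog <- function(manifest, stage, ...) {
  info <- list(...)
  message("[pleioscan] ", stage, ": ",
          paste(names(info), unlist(info), sep = "=", collapse = ", "))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the full pleiotropy pipeline
#'
#' Executes QC, harmonization, test-statistic covariance estimation,
#' joint scans over every configured trait subset (all pairs plus the
#' full set by default), pleiotropy classification, genomic-control
#' lambda and QQ tables, optional gene-based tests, and writes
#' tab-delimited outputs plus a JSON run manifest recording seeds, input
#' digests and per-stage counts. Any stage error aborts with the stage
#' name.
#'
#' @param config RunConfig list (see \code{\link{defaultConfig}}).
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("configuration error:\n  ", paste(viol, collapse = "\n  "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("pleioscan")),
                   inputs = list(), stages = list(), outputs = list())
  stage <- "read+qc"
  traits <- tryCatch({
    lapply(names(config$sumstats), function(tl) {
      s <- config$sumstats[[tl]]
      manifest$inputs[[tl]] <<- unname(tools::md5sum(s$path))
      x <- readSumStats(s$path, columnMap = s$column_map,
                        traitLabel = tl)
      qcFilter(x, config$qc$maf_max_excl, config$qc$r2_min_excl,
               config$qc$dosvar_min_excl)
    })
  }, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e)))
  manifest <- .stageLog(manifest, stage,
                        n_traits = length(traits),
                        n_retained = paste(vapply(traits, function(t)
                          nrow(records(t)), integer(1)), collapse = "/"))

  stage <- "harmonize"
  aligned <- tryCatch(harmonizeTraits(traits), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e)))
  manifest <- .stageLog(manifest, stage,
                        n_aligned = nrow(snpInfo(aligned)))
  writeAligned(aligned, file.path(config$out_dir, "aligned.tsv"))

  stage <- "covariance"
  Z <- zMatrix(aligned)
  Sigma <- tryCatch(estimateCovariance(Z), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e)))
  manifest <- .stageLog(manifest, stage, mode = Sigma@mode,
                        m_used = Sigma@nSnps)

  stage <- "scan"
  labs <- traitLabels(Z)
  subsets <- config$traits
  if (is.null(subsets)) {
    subsets <- if (length(labs) >= 2)
      c(utils::combn(labs, 2, simplify = FALSE),
        if (length(labs) >= 3) list(labs)) else list(labs)
  }
  scans <- list()
  for (sub in subsets) {
    nm <- paste(sub, collapse = "_")
    scans[[nm]] <- tryCatch(
      jointScan(Z, Sigma, traits = sub, weights = config$weights,
                gws = config$gws, magnitudeFactor = config$factor,
                nominal = config$nominal),
      error = function(e)
        stop("stage '", stage, "' failed for subset {",
             paste(sub, collapse = ","), "}: ", conditionMessage(e)))
    data.table::fwrite(scans[[nm]],
                       file.path(config$out_dir,
                                 paste0("scan_", nm, ".tsv")),
                       sep = "\t")
  }
  manifest <- .stageLog(manifest, stage, n_subsets = length(scans))

  stage <- "classify"
  nPleio <- vapply(scans, function(s)
    sum(s$class != "not_pleiotropic"), integer(1))
  manifest <- .stageLog(manifest, stage,
                        n_flagged = paste(names(nPleio), nPleio,
                                          sep = ":", collapse = ","))

  stage <- "lambda+qq"
  lam <- vapply(scans, function(s) genomicLambda(s$p_joint), numeric(1))
  lamTab <- data.frame(subset = names(lam), lambda = as.numeric(lam))
  data.table::fwrite(lamTab, file.path(config$out_dir, "lambda.tsv"),
                     sep = "\t")
  for (nm in names(scans))
    data.table::fwrite(qqTable(scans[[nm]]$p_joint),
                       file.path(config$out_dir,
                                 paste0("qq_", nm, ".tsv")), sep = "\t")
  manifest <- .stageLog(manifest, stage,
                        lambda = paste(names(lam), round(lam, 3),
                                       sep = ":", collapse = ","))

  stage <- "gene_tests"
  if (isTRUE(config$gene_test$enabled)) {
    gt <- config$gene_test
    genes <- tryCatch(
      readGeneModels(gt$genes,
                     format = if (grepl("\\.bed$", gt$genes)) "bed"
                              else "tsv"),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e)))
    ref <- readDosages(gt$ref, format = gt$ref_format)
    for (nm in names(scans)) {
      res <- tryCatch(
        geneBasedScan(scans[[nm]], genes, ref, pColumn = gt$p_column,
                      window = gt$window, stages = gt$stages,
                      seed = gt$seed),
        error = function(e)
          stop("stage '", stage, "' failed for subset ", nm, ": ",
               conditionMessage(e)))
      data.table::fwrite(res, file.path(config$out_dir,
                                        paste0("genes_", nm, ".tsv")),
                         sep = "\t")
    }
    manifest <- .stageLog(manifest, stage, n_genes = nrow(genes),
                          seed = gt$seed)
  } else {
    manifest <- .stageLog(manifest, stage, enabled = FALSE)
  }

  outs <- list.files(config$out_dir, pattern = "\\.tsv$",
                     full.names = TRUE)
  manifest$outputs <- as.list(tools::md5sum(outs))
  names(manifest$outputs) <- basename(outs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
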