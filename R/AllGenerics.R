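#' @rdname TraitSumStats-class
#' @param object,x a \code{TraitSumStats} (or other pleioscan) object
#' @export
setGeneric("traitLabel", function(object) standardGeneric("traitLabel"))

#' @rdname TraitSumStats-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname TraitSumStats-class
#' @export
setGeneric("qcReport", function(object) standardGeneric("qcReport"))

#' @rdname ZMatrix-class
#' @param object a pleioscan object carrying SNP coordinates
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' @rdname ZMatrix-class
#' @export
setGeneric("traitLabels", function(object) standardGeneric("traitLabels"))

#' @rdname ZMatrix-class
#' @export
setGeneric("zValues", function(object) standardGeneric("zValues"))

#' @rdname AlignedSumStats-class
#' @param object an \code{AlignedSumStats}
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))

#' @rdname TestCovariance-class
#' @param object a \code{TestCovariance} or \code{LDMatrix}
#' @export
setGeneric("covMatrix", function(object) standardGeneric("covMatrix"))

setMethod("traitLabel", "TraitSumStats", function(object) object@traitLabel)
setMethod("records", "TraitSumStats", function(object) object@records)
setMethod("qcReport", "TraitSumStats", function(object) object@report)
setMethod("qcReport", "AlignedSumStats", function(object) object@report)

setMethod("snpInfo", "ZMatrix", function(object) object@snpInfo)
setMethod("snpInfo", "AlignedSumStats", function(object) object@snpInfo)
setMethod("snpInfo", "SyntheticStudy", function(object) object@snpMap)
setMethod("traitLabels", "ZMatrix", function(object) object@traits)
setMethod("traitLabels", "AlignedSumStats", function(object) object@traits)
setMethod("zValues", "ZMatrix", function(object) object@z)
setMethod("zValues", "AlignedSumStats", function(object) object@z)

setMethod("zMatrix", "AlignedSumStats", function(object) {
  new("ZMatrix", z = object@z,
      snpInfo = object@snpInfo[, c("snp_id", "chrom", "pos")],
      traits = object@traits)
})

setMethod("covMatrix", "TestCovariance", function(object) object@sigma)
setMethod("covMatrix", "LDMatrix", function(object) object@R)

setMethod("show", "TraitSumStats", function(object) {
  cat("TraitSumStats for trait", sQuote(object@traitLabel), "with",
      nrow(object@records), "SNPs\n")
  if (length(object@report))
    cat("  report:", paste(names(object@report), unlist(object@report),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AlignedSumStats", function(object) {
  cat("AlignedSumStats:", nrow(object@snpInfo), "SNPs x",
      length(object@traits), "traits (",
      paste(object@traits, collapse = ", "), ")\n")
})

setMethod("show", "ZMatrix", function(object) {
  cat("ZMatrix:", nrow(object@z), "SNPs x", length(object@traits),
      "traits (", paste(object@traits, collapse = ", "), ")\n")
})

setMethod("show", "TestCovariance", function(object) {
  cat("TestCovariance (mode", sQuote(object@mode), ", M =",
      object@nSnps, "):\n")
  print(round(object@sigma, 4))
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix:", length(object@snpIds), "SNPs, shrinkage =",
      signif(object@shrinkage, 3), "\n")
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nrow(object@dosages), "subjects x",
      ncol(object@dosages), "SNPs;",
      sum(object@phenotypes$status == "AD"), "AD /",
      sum(object@phenotypes$status != "AD"), "control;",
      nrow(object@truth$causal), "causal SNPs (seed",
      object@seed, ")\n")
})
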