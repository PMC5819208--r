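#' Published worked-example loci for the pleiotropy declaration rule
#'
#' Reported univariate (NP, NFT, CAA) effect sizes and p-values and joint
#' p-values for the three trait pairs at two AD-neuropathology loci
#' (rs34487851 near \emph{C2orf40}, rs79524815 in \emph{HDAC9}), bundled
#' as a worked example for \code{\link{classifyPleiotropy}}: applying the
#' declaration rule across both SNPs and all three pairs yields exactly
#' two genome-wide-significant pleiotropic (SNP, pair) combinations.
#'
#' @return data.frame of the bundled table.
#' @export
workedExampleLoci <- function() {
  path <- system.file("extdata", "worked_example_loci.tsv",
                      package = "pleioscan", mustWork = TRUE)
  data.table::fread(path, data.table = FALSE, showProgress = FALSE)
}

#' Classify the worked-example loci across all trait pairs
#'
#' Runs \code{\link{classifyPleiotropy}} on every (SNP, trait-pair)
#' combination of \code{\link{workedExampleLoci}}.
#'
#' @param gws,magnitudeFactor,nominal rule parameters (defaults as in the
#'   scan).
#' @return data.frame: snp_id, pair, p_joint, p_univ_1, p_univ_2, class.
#' @export
classifyWorkedExample <- function(gws = 5e-8, magnitudeFactor = 10,
                                  nominal = 0.05) {
  tab <- workedExampleLoci()
  pairs <- list(c("NP", "NFT"), c("NP", "CAA"), c("NFT", "CAA"))
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (pr in pairs) {
      pj <- tab[[paste0("p_joint_", pr[1], "_", pr[2])]][i]
      pu <- c(tab[[paste0("p_", pr[1])]][i],
              tab[[paste0("p_", pr[2])]][i])
      cls <- classifyPleiotropy(pj, matrix(pu, 1), gws = gws,
                                magnitudeFactor = magnitudeFactor,
                                nominal = nominal)
      rows[[length(rows) + 1L]] <-
        data.frame(snp_id = tab$snp_id[i],
                   pair = paste(pr, collapse = "+"),
                   p_joint = pj, p_univ_1 = pu[1], p_univ_2 = pu[2],
                   class = as.character(cls),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
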