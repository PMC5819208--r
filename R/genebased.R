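#' Read gene models from BED or 1-based four-column text
#'
#' BED input (0-based, half-open) is converted to 1-based inclusive
#' coordinates on read; \code{"tsv"} expects header-less or headered
#' columns gene, chrom, start, end already 1-based inclusive.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return data.frame: \code{gene_id}, \code{chrom}, \code{tx_start},
#'   \code{tx_end}, \code{strand} (annotation only; \code{"*"} when
#'   absent).
#' @export
readGeneModels <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE,
                          showProgress = FALSE)
  if (format == "bed") {
    out <- data.frame(gene_id = as.character(dt[[4]]),
                      chrom = sub("^chr", "", as.character(dt[[1]])),
                      tx_start = as.integer(dt[[2]]) + 1L,
                      tx_end = as.integer(dt[[3]]),
                      strand = if (ncol(dt) >= 6) as.character(dt[[6]])
                               else "*",
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene_id = as.character(dt[[1]]),
                      chrom = sub("^chr", "", as.character(dt[[2]])),
                      tx_start = as.integer(dt[[3]]),
                      tx_end = as.integer(dt[[4]]),
                      strand = if (ncol(dt) >= 5) as.character(dt[[5]])
                               else "*",
                      stringsAsFactors = FALSE)
  }
  if (any(out$tx_start > out$tx_end))
    stop("input error: gene with tx_start > tx_end: ",
         out$gene_id[which(out$tx_start > out$tx_end)[1]])
  out
}

#' Assign SNPs to gene windows
#'
#' A SNP belongs to a gene when it lies within \code{window} bp of the
#' transcript span: \code{tx_start - window <= pos <= tx_end + window},
#' bounds inclusive. A SNP may belong to several genes. Implemented with
#' \code{GenomicRanges::findOverlaps}.
#'
#' @param snps data.frame with \code{snp_id}, \code{chrom}, \code{pos}.
#' @param genes data.frame as returned by \code{\link{readGeneModels}}.
#' @param window flank size in bp (default 30000).
#' @return named list (one element per gene with >= 1 SNP) of integer row
#'   indices into \code{snps}; genes with zero SNPs are reported in the
#'   \code{"empty_genes"} attribute and skipped.
#' @export
assignSnpsToGenes <- function(snps, genes, window = 30000L) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "tx_start", "tx_end") %in%
                  names(genes)),
            window >= 0)
  lvls <- unique(c(as.character(snps$chrom), as.character(genes$chrom)))
  sg <- GenomicRanges::GRanges(
    factor(as.character(snps$chrom), levels = lvls),
    IRanges::IRanges(snps$pos, snps$pos))
  gg <- GenomicRanges::GRanges(
    factor(as.character(genes$chrom), levels = lvls),
    IRanges::IRanges(pmax(1L, genes$tx_start - as.integer(window)),
                     genes$tx_end + as.integer(window)))
  hits <- GenomicRanges::findOverlaps(sg, gg)
  byGene <- split(S4Vectors::queryHits(hits),
                  genes$gene_id[S4Vectors::subjectHits(hits)])
  byGene <- lapply(byGene, function(ix) sort(unique(ix)))
  empty <- setdiff(genes$gene_id, names(byGene))
  structure(byGene[intersect(genes$gene_id, names(byGene))],
            empty_genes = empty)
}

#' LD correlation matrix from reference dosages
#'
#' Pearson correlation of the dosage columns (0-2 scale), shrunk linearly
#' toward the identity by the smallest intensity that lifts the minimum
#' eigenvalue to at least 1e-8, so the matrix is usable as a multivariate
#' normal correlation.
#'
#' @param dosages sample x SNP numeric matrix with SNP ids as colnames.
#' @param shrink fixed shrinkage in [0, 1), or \code{"auto"} (default).
#' @return an \code{\link{LDMatrix}}.
#' @export
ldFromGenotypes <- function(dosages, shrink = "auto") {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) >= 2)
  sds <- apply(dosages, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(dosages)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("input error: monomorphic SNP(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  R <- cor(dosages)
  R <- (R + t(R)) / 2
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(dosages)))
  if (identical(shrink, "auto")) {
    emin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    lam <- if (emin >= 1e-8) 0 else (1e-8 - emin) / (1 - emin)
  } else {
    stopifnot(is.numeric(shrink), shrink >= 0, shrink < 1)
    lam <- shrink
  }
  if (lam > 0) {
    R <- (1 - lam) * R
    diag(R) <- 1
  }
  new("LDMatrix", R = R, snpIds = ids, shrinkage = lam)
}

#' VEGAS gene statistic
#'
#' Sum of per-SNP 1-df chi-square statistics obtained from the upper-tail
#' quantile of each SNP's p-value.
#'
#' @param p per-SNP p-values in (0, 1].
#' @return the observed gene statistic Q.
#' @export
geneStatistic <- function(p) {
  if (length(p) == 0L) stop("input error: empty SNP set for gene")
  if (any(p <= 0 | p > 1)) stop("input error: p-values must lie in (0, 1]")
  sum(qchisq(p, df = 1, lower.tail = FALSE))
}

## draw nSims null gene statistics Q* = sum z*^2 with z* ~ MVN(0, R)
.simulateNullQ <- function(nSims, Rchol) {
  S <- ncol(Rchol)
  ## chunk so memory stays bounded for the 1e6 stage
  chunk <- max(1L, min(nSims, as.integer(ceiling(2e7 / S))))
  out <- numeric(nSims)
  done <- 0L
  while (done < nSims) {
    m <- min(chunk, nSims - done)
    zm <- matrix(rnorm(m * S), m, S) %*% Rchol
    out[(done + 1L):(done + m)] <- rowSums(zm * zm)
    done <- done + m
  }
  out
}

.ldChol <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- tryCatch(eigen(R, symmetric = TRUE), error = function(e)
      stop("numerical error: eigendecomposition of LD matrix failed"))
    ev <- pmax(eg$values, 0)
    ch <- t(eg$vectors %*% (t(eg$vectors) * sqrt(ev)))
  }
  ch
}

#' Monte-Carlo empirical p-value for a gene statistic
#'
#' Simulates null gene statistics from a multivariate normal with the gene
#' window's LD correlation matrix and returns the
#' \code{(exceedances + 1) / (simulations + 1)} empirical p-value, which is
#' never zero: with the default 1e6 ceiling and no exceedances the floor is
#' about 1.0e-6. Simulation escalates to the next stage only while fewer
#' than 10 exceedances have been seen (adaptive staging); the result is
#' reproducible given the seed.
#'
#' @param Q observed gene statistic.
#' @param R an \code{\link{LDMatrix}} (or correlation matrix).
#' @param stages increasing total simulation counts (default
#'   \code{c(1e3, 1e4, 1e6)}).
#' @param seed integer seed (required).
#' @param gene_id optional label carried into the result.
#' @return one-row data.frame: \code{gene_id}, \code{n_snps},
#'   \code{q_observed}, \code{n_sims_final}, \code{n_exceed},
#'   \code{empirical_p}.
#' @export
geneEmpiricalP <- function(Q, R, stages = c(1e3, 1e4, 1e6), seed,
                           gene_id = NA_character_) {
  stopifnot(is.numeric(Q), Q >= 0, !missing(seed),
            all(diff(stages) > 0), all(stages >= 1))
  Rm <- if (is(R, "LDMatrix")) R@R else as.matrix(R)
  ch <- .ldChol(Rm)
  set.seed(as.integer(seed))
  nSims <- 0L
  nExceed <- 0L
  for (s in as.integer(stages)) {
    add <- s - nSims
    if (add > 0) {
      q0 <- .simulateNullQ(add, ch)
      nExceed <- nExceed + sum(q0 >= Q)
      nSims <- s
    }
    if (nExceed >= 10L) break
  }
  data.frame(gene_id = gene_id, n_snps = ncol(Rm), q_observed = Q,
             n_sims_final = nSims, n_exceed = nExceed,
             empirical_p = (nExceed + 1) / (nSims + 1),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' \code{alpha / nTests}, returned at full precision with a 3-significant-
#' digit display value attached as the \code{"display"} attribute (e.g.
#' 0.05 over 18,500 genes gives 2.70e-6).
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param nTests positive number of tests.
#' @return threshold (numeric scalar with a \code{display} attribute).
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  th <- alpha / nTests
  structure(th, display = signif(th, 3))
}

#' Gene-based scan over a joint (or univariate) SNP p-value table
#'
#' For each gene: collect SNPs within the window, build the LD matrix from
#' the reference dosages, form the VEGAS statistic from the SNP p-values
#' and compute its Monte-Carlo empirical p. Genes with no SNPs, or whose
#' window SNPs are absent from the reference panel, are skipped with a
#' report. Per-gene seeds are derived deterministically from \code{seed}.
#'
#' @param scan data.frame with \code{snp_id}, \code{chrom}, \code{pos} and
#'   the p-value column named by \code{pColumn}.
#' @param genes gene-model data.frame (see \code{\link{readGeneModels}}).
#' @param refDosages sample x SNP dosage matrix, colnames matching
#'   \code{snp_id}.
#' @param pColumn name of the p-value column (default \code{"p_joint"}).
#' @param window flank in bp.
#' @param stages,seed see \code{\link{geneEmpiricalP}}.
#' @return data.frame with one row per tested gene (columns of
#'   \code{\link{geneEmpiricalP}}); skipped genes in attribute
#'   \code{"skipped"}.
#' @export
geneBasedScan <- function(scan, genes, refDosages, pColumn = "p_joint",
                          window = 30000L, stages = c(1e3, 1e4, 1e6),
                          seed) {
  stopifnot(pColumn %in% names(scan), !missing(seed))
  assign <- assignSnpsToGenes(scan, genes, window = window)
  skipped <- attr(assign, "empty_genes")
  rows <- list()
  for (g in names(assign)) {
    ix <- assign[[g]]
    ids <- intersect(scan$snp_id[ix], colnames(refDosages))
    if (length(ids) == 0L) {
      skipped <- c(skipped, g)
      next
    }
    ix <- ix[scan$snp_id[ix] %in% ids]
    R <- ldFromGenotypes(refDosages[, scan$snp_id[ix], drop = FALSE])
    Q <- geneStatistic(scan[[pColumn]][ix])
    gSeed <- (as.integer(seed) + match(g, names(assign)) * 7919L) %%
      .Machine$integer.max
    rows[[g]] <- geneEmpiricalP(Q, R, stages = stages, seed = gSeed,
                                gene_id = g)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  structure(out, skipped = skipped)
}
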