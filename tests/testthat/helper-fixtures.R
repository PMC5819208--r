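# shared fixture builders; everything is generated in code

writeSumStatsFile <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small well-formed summary-statistics data.frame
tinySumStatsDf <- function(n = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = "1",
    pos = 1000L * seq_len(n),
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    ref_allele = rep(c("G", "T", "T"), length.out = n),
    eaf = round(runif(n, 0.05, 0.95), 3),
    beta = round(rnorm(n, 0, 0.2), 4),
    se = round(runif(n, 0.03, 0.2), 4),
    stringsAsFactors = FALSE)
}

tinyTraitSumStats <- function(n = 3, seed = 1, label = "NP") {
  readSumStats(writeSumStatsFile(tinySumStatsDf(n, seed)),
               traitLabel = label)
}

# equicorrelated KxK matrix
equicorr <- function(K, rho) {
  S <- matrix(rho, K, K)
  diag(S) <- 1
  S
}

# flip effect/ref alleles and beta sign of a TraitSumStats (same model,
# opposite orientation)
flipOrientation <- function(x) {
  rec <- records(x)
  tmp <- rec$effect_allele
  rec$effect_allele <- rec$ref_allele
  rec$ref_allele <- tmp
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  new("TraitSumStats", traitLabel = traitLabel(x), records = rec)
}
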