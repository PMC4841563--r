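# Fixtures are generated in code; nothing is stored on disk.

# small dense genotype region with i.i.d. binomial dosages
make_region <- function(n = 50, p = 6, maf = NULL, seed = 1,
                        region_id = "fix") {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  repeat {
    dos <- sapply(maf, function(q) rbinom(n, 2, q))
    if (all(apply(dos, 2, var) > 0)) break
  }
  genotype_region(dos, positions = sort(sample.int(10000, p)),
                  region_id = region_id)
}

# a toy VCF on disk; genotypes given as a variants x samples matrix of
# GT strings
write_toy_vcf <- function(gt, pos, path = tempfile(fileext = ".vcf"),
                          chrom = "1", ref = "A", alt = "C",
                          samples = paste0("S", seq_len(ncol(gt)))) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c(chrom, pos[i], paste0("v", i), ref, alt, ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# discrete-profile FPCA configuration used by the PCA-equivalence oracles
discrete_cfg <- function(...) {
  fpca_control(smoothing = "none", quadrature = "uniform",
               variance_threshold = 1, ...)
}

# row-subset / permute a region's samples
subset_rows <- function(region, idx) {
  genotype_region(region$dosage[idx, , drop = FALSE], region$positions,
                  region$chrom, region$region_id)
}

# correlated null traits + two common-variant genes, the workhorse fixture
# for the statistic-level tests
make_pair_fixture <- function(n = 200, p = 8, K = 2, seed = 1) {
  set.seed(seed)
  list(g1 = make_region(n, p, seed = seed + 1, region_id = "gene1"),
       g2 = make_region(n, p, seed = seed + 2, region_id = "gene2"),
       Y = matrix(rnorm(n * K), n, K) %*% chol(matrix(0.5, K, K) + diag(0.5, K)))
}
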