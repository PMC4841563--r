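#' Synthetic haplotype pool
#'
#' Builds a pool of binary haplotypes emulating resampling from a sequenced
#' population.  Per-variant minor allele frequencies are drawn from the
#' configured spectrum: `"common"` is Uniform(0.05, 0.5); `"rare"` is a Beta
#' draw scaled to (1/n_hap, 0.01); `"mixed"` mixes the two (half each).
#'
#' Linkage structure: for common variants the default (`ld = "founder"`)
#' builds each pool haplotype as a segment mosaic of a small founder set
#' (`n_founders` founder haplotypes, switching founder with probability
#' `switch_rate` at each successive variant).  That mirrors the low
#' common-haplotype diversity of a real gene, and is what makes the
#' functional expansion low-dimensional ("a few" components).  Rare variants
#' are recent and essentially unlinked, so under the rare spectrum alleles
#' are placed i.i.d. Bernoulli(MAF) regardless of `ld`; `ld = "none"` does
#' the same for common variants.
#'
#' @param n_hap number of haplotypes (even, at least twice the largest
#'   sample you will draw).
#' @param n_variants number of variant sites.
#' @param maf_spectrum `"common"`, `"rare"` or `"mixed"`.
#' @param positions_model `"uniform"` (sorted uniform positions over
#'   `region_length`) or `"equispaced"`.
#' @param region_length region span in bp.
#' @param ld `"founder"` or `"none"`.
#' @param n_founders founder haplotypes for the mosaic (default 6: a typical
#'   gene carries only a handful of common haplotypes).
#' @param switch_rate per-variant founder switch probability.
#' @param rare_shape shape parameters of the Beta spectrum for rare MAFs.
#' @param seed RNG seed (required for reproducibility).
#' @return Object of class `haplotype_pool`: `haplotypes` (n_hap x
#'   n_variants 0/1 matrix), `positions`, `maf` (target), `maf_realized`,
#'   `maf_spectrum`, `seed`.
#' @export
haplotype_pool <- function(n_hap, n_variants,
                           maf_spectrum = c("common", "rare", "mixed"),
                           positions_model = c("uniform", "equispaced"),
                           region_length = 10000,
                           ld = c("founder", "none"),
                           n_founders = 6, switch_rate = 0.01,
                           rare_shape = c(0.5, 3), seed = NULL) {
  maf_spectrum <- match.arg(maf_spectrum)
  positions_model <- match.arg(positions_model)
  ld <- match.arg(ld)
  stopifnot(n_hap >= 4, n_hap %% 2 == 0, n_variants >= 1)
  if (!is.null(seed)) set.seed(seed)
  positions <- if (positions_model == "uniform")
    sort(sample.int(region_length, n_variants)) else
      round(seq(1, region_length, length.out = n_variants))
  draw_maf <- function(m, spectrum) {
    switch(spectrum,
           common = stats::runif(m, 0.05, 0.5),
           rare = {
             lo <- 1 / n_hap
             if (lo >= 0.01) stop_mfrg("n_hap too small for a rare spectrum",
                                       "mfrg_bad_input")
             lo + (0.01 - lo) * stats::rbeta(m, rare_shape[1], rare_shape[2])
           })
  }
  spectra <- if (maf_spectrum == "mixed") {
    sample(rep(c("rare", "common"), length.out = n_variants))
  } else rep(maf_spectrum, n_variants)
  maf <- vapply(spectra, function(s) draw_maf(1, s), numeric(1))
  H <- matrix(0L, n_hap, n_variants)
  common_idx <- which(spectra == "common")
  rare_idx <- which(spectra == "rare")
  if (length(common_idx)) {
    if (ld == "founder") {
      # founder alleles: carrier count round(maf * n_founders), clamped to
      # [1, floor(n_founders/2)] so the pool frequency stays in the band
      nf <- n_founders
      founders <- matrix(0L, nf, length(common_idx))
      for (k in seq_along(common_idx)) {
        cnt <- max(1L, min(as.integer(floor(nf / 2)),
                           as.integer(round(maf[common_idx[k]] * nf))))
        founders[sample.int(nf, cnt), k] <- 1L
        maf[common_idx[k]] <- cnt / nf
      }
      # mosaic haplotypes: switch founder with prob switch_rate per variant
      m <- length(common_idx)
      state <- sample.int(nf, n_hap, replace = TRUE)
      for (k in seq_len(m)) {
        if (k > 1) {
          sw <- stats::runif(n_hap) < switch_rate
          if (any(sw)) state[sw] <- sample.int(nf, sum(sw), replace = TRUE)
        }
        H[, common_idx[k]] <- founders[state, k]
      }
    } else {
      for (k in common_idx)
        H[, k] <- as.integer(stats::runif(n_hap) < maf[k])
    }
  }
  for (k in rare_idx)
    H[, k] <- as.integer(stats::runif(n_hap) < maf[k])
  # keep every site polymorphic and on the minor strand in the pool
  for (k in seq_len(n_variants)) {
    s <- sum(H[, k])
    if (s == 0) H[sample.int(n_hap, 1), k] <- 1L
    if (s == n_hap) H[sample.int(n_hap, 1), k] <- 0L
    if (sum(H[, k]) > n_hap / 2) H[, k] <- 1L - H[, k]
  }
  structure(
    list(haplotypes = H, positions = positions, maf = maf,
         maf_realized = colMeans(H), maf_spectrum = maf_spectrum,
         ld = ld, seed = seed),
    class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants (%s spectrum, ld = %s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$maf_spectrum, x$ld))
  invisible(x)
}

#' Sample diploid genotypes from a haplotype pool
#'
#' Draws two haplotypes per individual with replacement and sums them into a
#' dosage matrix.
#'
#' @param pool a [haplotype_pool()].
#' @param n_samples number of individuals.
#' @param seed optional RNG seed.
#' @param region_id label for the returned region.
#' @return A [genotype_region()].
#' @export
sample_genotypes <- function(pool, n_samples, seed = NULL,
                             region_id = "simulated") {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (!is.null(seed)) set.seed(seed)
  n_hap <- nrow(pool$haplotypes)
  i1 <- sample.int(n_hap, n_samples, replace = TRUE)
  i2 <- sample.int(n_hap, n_samples, replace = TRUE)
  dos <- pool$haplotypes[i1, , drop = FALSE] + pool$haplotypes[i2, , drop = FALSE]
  genotype_region(dos, pool$positions, region_id = region_id)
}

#' Frequency-centered dosage coding
#'
#' Maps counts of allele A (frequency `P`) to `2(1-P)`, `1-2P`, `-2P` for
#' genotypes AA, Aa, aa — i.e. `dosage - 2P`, which has population mean zero
#' under Hardy-Weinberg equilibrium.
#'
#' @param dosage counts of allele A in \{0, 1, 2\} (vector or matrix).
#' @param P allele-A frequency (scalar, or one per dosage column).
#' @export
centered_dosage <- function(dosage, P) {
  if (!all(P > 0 & P < 1))
    stop_mfrg("allele frequency P must lie strictly in (0, 1)",
              "mfrg_bad_input")
  if (is.matrix(dosage)) sweep(dosage, 2, 2 * P) else dosage - 2 * P
}

# exchangeable correlation matrix
exch_cor <- function(K, rho = 0.5) {
  R <- matrix(rho, K, K); diag(R) <- 1; R
}

# n x K correlated Gaussian noise with exchangeable correlation
mvn_noise <- function(n, K, rho = 0.5) {
  Z <- matrix(stats::rnorm(n * K), n, K)
  if (K > 1) Z <- Z %*% chol(exch_cor(K, rho))
  Z
}

#' Simulate multi-trait phenotypes under the no-interaction null
#'
#' Three nested null scenarios: `"null"` (traits are pure correlated noise,
#' `Y = mu + eps`), `"marginal_one_gene"` (additive marginal effects at gene
#' 1 only) and `"marginal_two_genes"` (additive marginal effects at both
#' genes).  Marginal effect sizes are `alpha_k = (r_k - 1) * f0` with per-
#' trait risk parameters drawn uniformly from `risk_range`; genotypes enter
#' through the frequency-centered coding [centered_dosage()].  No
#' interaction term is ever included.
#'
#' @param n sample size (ignored when genotypes are supplied: their row
#'   count is used).
#' @param K number of traits.
#' @param scenario one of `"null"`, `"marginal_one_gene"`,
#'   `"marginal_two_genes"`.
#' @param region1,region2 [genotype_region()] objects (required by the
#'   marginal scenarios).
#' @param freq1,freq2 population allele frequencies of the coded alleles
#'   (default: pool/realized frequencies stored in the regions).
#' @param rho exchangeable trait correlation.
#' @param mu length-K trait means.
#' @param risk_range range of the marginal risk parameters.
#' @param f0 baseline penetrance scale.
#' @param seed optional RNG seed.
#' @return n x K trait matrix.
#' @export
simulate_null_traits <- function(n = NULL, K = 5,
                                 scenario = c("null", "marginal_one_gene",
                                              "marginal_two_genes"),
                                 region1 = NULL, region2 = NULL,
                                 freq1 = NULL, freq2 = NULL,
                                 rho = 0.5, mu = rep(0, K),
                                 risk_range = c(1.1, 1.6), f0 = 1,
                                 seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  if (scenario != "null" && is.null(region1))
    stop_mfrg("marginal scenarios need genotype regions", "mfrg_bad_input")
  if (scenario == "marginal_two_genes" && is.null(region2))
    stop_mfrg("marginal_two_genes needs both regions", "mfrg_bad_input")
  if (is.null(n)) n <- nrow(region1$dosage)
  Y <- matrix(rep(mu, each = n), n, K) + mvn_noise(n, K, rho)
  add_marginal <- function(Y, region, freq) {
    if (is.null(freq)) freq <- colMeans(region$dosage) / 2
    freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
    x <- centered_dosage(region$dosage, freq)
    r <- stats::runif(K, risk_range[1], risk_range[2])
    Y + as.numeric(rowSums(x)) %o% ((r - 1) * f0)
  }
  if (scenario %in% c("marginal_one_gene", "marginal_two_genes"))
    Y <- add_marginal(Y, region1, freq1)
  if (scenario == "marginal_two_genes")
    Y <- add_marginal(Y, region2, freq2)
  colnames(Y) <- paste0("trait", seq_len(K))
  Y
}

#' Two-locus genotypic value under a penetrance-table interaction model
#'
#' Returns the genotypic mean (0 or `r`) for each pair of risk-allele
#' counts.  Models: `dom_or_dom` — value `r` iff at least one risk allele at
#' either locus; `dom_and_dom` — `r` iff at least one risk allele at *both*
#' loci; `rec_or_rec` — `r` iff homozygous risk at either locus;
#' `threshold` — `r` iff homozygous risk at one locus and at least one risk
#' allele at the other (applied symmetrically in the two loci).
#'
#' @param g1_copies,g2_copies risk-allele counts in \{0, 1, 2\} (vectors
#'   recycled to common length).
#' @param model one of `"dom_or_dom"`, `"dom_and_dom"`, `"rec_or_rec"`,
#'   `"threshold"`.
#' @param r risk parameter (trait mean of the affected genotype classes).
#' @export
genotypic_value <- function(g1_copies, g2_copies,
                            model = c("dom_or_dom", "dom_and_dom",
                                      "rec_or_rec", "threshold"),
                            r = 1) {
  model <- match.arg(model)
  if (!all(g1_copies %in% 0:2) || !all(g2_copies %in% 0:2))
    stop_mfrg("allele copies must be 0, 1 or 2", "mfrg_bad_input")
  hit <- switch(model,
    dom_or_dom  = g1_copies >= 1 | g2_copies >= 1,
    dom_and_dom = g1_copies >= 1 & g2_copies >= 1,
    rec_or_rec  = g1_copies == 2 | g2_copies == 2,
    threshold   = (g1_copies == 2 & g2_copies >= 1) |
                  (g2_copies == 2 & g1_copies >= 1))
  r * as.numeric(hit)
}

#' Select causal variants of a region
#'
#' Randomly marks `fraction` of the variants (at least one) as causal.
#' @param region a [genotype_region()], [haplotype_pool()], or a plain
#'   variant count.
#' @param fraction causal fraction (default 0.2).
#' @param seed optional RNG seed.
#' @return integer vector of causal column indices.
#' @export
select_causal <- function(region, fraction = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (inherits(region, "genotype_region")) ncol(region$dosage)
       else if (inherits(region, "haplotype_pool")) ncol(region$haplotypes)
       else as.integer(region)
  m <- max(1L, round(fraction * p))
  sort(sample.int(p, m))
}

#' Simulate multi-trait phenotypes under a two-locus interaction model
#'
#' Trait value of individual u is the per-trait genotypic value summed over
#' the H causal QTL pairs plus correlated Gaussian noise.  The genotypic
#' value is trait-specific: with `trait_effects = "signed"` (default) trait
#' m receives the genotypic sum scaled by an independent random sign, so
#' the epistatic effect has magnitude `r` in every trait but its direction
#' differs across traits — the pleiotropic pattern (e.g. a variant pair
#' raising one lipid trait while lowering another) that makes joint
#' multi-trait testing profitable.  `trait_effects = "shared"` gives every
#' trait the identical sum; in that case the signal is confined to the
#' equicorrelated direction of the trait space, where exchangeable noise is
#' largest, and multi-trait power saturates rather than grows with K.
#' Causal pairs are formed by pairing the i-th causal variant of gene 1
#' with the i-th of gene 2, recycling the shorter list
#' (`pairing = "recycle"`), or by crossing all causal variants
#' (`pairing = "all"`).
#'
#' @param region1,region2 [genotype_region()] objects.
#' @param causal1,causal2 causal column indices per gene (see
#'   [select_causal()]).
#' @param model interaction model, see [genotypic_value()].
#' @param r risk parameter (`r = 0` reduces to the pure null).
#' @param K number of traits.
#' @param rho exchangeable trait correlation.
#' @param trait_effects `"signed"` or `"shared"` (see above).
#' @param pairing `"recycle"` or `"all"`.
#' @param seed optional RNG seed.
#' @return n x K trait matrix.
#' @export
simulate_power_traits <- function(region1, region2, causal1, causal2,
                                  model = "dom_or_dom", r = 0.2, K = 2,
                                  rho = 0.5,
                                  trait_effects = c("signed", "shared"),
                                  pairing = c("recycle", "all"),
                                  seed = NULL) {
  pairing <- match.arg(pairing)
  trait_effects <- match.arg(trait_effects)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(region1$dosage)
  pairs <- if (pairing == "all") {
    as.matrix(expand.grid(causal1, causal2))
  } else {
    H <- max(length(causal1), length(causal2))
    cbind(rep_len(causal1, H), rep_len(causal2, H))
  }
  gsum <- numeric(n)   # indicator sum; scaled per trait below
  for (h in seq_len(nrow(pairs))) {
    gsum <- gsum + genotypic_value(region1$dosage[, pairs[h, 1]],
                                   region2$dosage[, pairs[h, 2]],
                                   model = model, r = 1)
  }
  s <- if (trait_effects == "signed")
    r * sample(c(-1, 1), K, replace = TRUE) else rep(r, K)
  Y <- gsum %o% s + mvn_noise(n, K, rho)
  colnames(Y) <- paste0("trait", seq_len(K))
  Y
}

#' Type-I-error experiment
#'
#' Monte-Carlo estimate of the empirical rejection rate of an interaction
#' test under a chosen null scenario.  Per replicate: diploid genotypes for
#' both genes are drawn from fixed haplotype pools, traits are simulated
#' with [simulate_null_traits()], and the test is run; the rejection rate at
#' each nominal level is the fraction of replicates with p below it, with a
#' normal-approximation binomial confidence interval attached.
#'
#' @param pool1,pool2 [haplotype_pool()] objects for the two genes.
#' @param n sample size per replicate.
#' @param K number of traits.
#' @param scenario null scenario, see [simulate_null_traits()].
#' @param n_replicates number of replicates (>= 100).
#' @param alphas nominal significance levels.
#' @param method `"wald"` or `"lrt"`.
#' @param fpca an [fpca_control()].
#' @param rho exchangeable trait correlation.
#' @param conf confidence level of the reported binomial interval.
#' @param seed RNG seed; per-replicate sub-seeds are derived from it.
#' @return data.frame: `alpha`, `rate`, `ci_low`, `ci_high`, `n`,
#'   `n_replicates`; the replicate p-values are attached as
#'   `attr(, "p_values")`.
#' @export
run_type1_experiment <- function(pool1, pool2, n = 1000, K = 5,
                                 scenario = "marginal_two_genes",
                                 n_replicates = 1000,
                                 alphas = c(0.05, 0.01, 0.001),
                                 method = c("wald", "lrt"),
                                 fpca = fpca_control(), rho = 0.5,
                                 conf = 0.99, seed = 1) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 100)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  pv <- vapply(rep_seeds, function(s) {
    set.seed(s)
    g1 <- sample_genotypes(pool1, n, region_id = "gene1")
    g2 <- sample_genotypes(pool2, n, region_id = "gene2")
    Y <- simulate_null_traits(n, K, scenario, g1, g2,
                              freq1 = pool1$maf_realized,
                              freq2 = pool2$maf_realized, rho = rho)
    muffle_rank_warnings(
      test_gene_pair(g1, g2, Y, cfg = fpca, method = method)$p.value)
  }, numeric(1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rate <- vapply(alphas, function(a) mean(pv <= a), numeric(1))
  half <- z * sqrt(rate * (1 - rate) / n_replicates)
  out <- data.frame(alpha = alphas, rate = rate,
                    ci_low = pmax(0, rate - half),
                    ci_high = pmin(1, rate + half),
                    n = n, n_replicates = n_replicates)
  attr(out, "p_values") <- pv
  out
}

#' Power experiment across interaction strengths and methods
#'
#' Monte-Carlo power of the gene-based tests under a two-locus penetrance
#' model.  Causal variants (20% of each gene by default) are fixed per pool;
#' genotypes are redrawn each replicate.  Methods: `"mfrg"` (multi-trait
#' Wald), `"sfrg"` (single-trait functional test on trait 1), `"pca"`
#' (regression on ordinary principal components) and `"pairwise"`
#' (permutation-adjusted max pairwise SNP test).
#'
#' @param pool1,pool2 [haplotype_pool()] objects.
#' @param n sample size per replicate.
#' @param K number of traits.
#' @param model interaction model, see [genotypic_value()].
#' @param r_grid risk-parameter grid.
#' @param methods subset of `c("mfrg", "sfrg", "pca", "pairwise")`.
#' @param n_replicates replicates per grid point.
#' @param alpha significance level.
#' @param causal_fraction causal fraction per gene.
#' @param fpca an [fpca_control()].
#' @param rho exchangeable trait correlation.
#' @param n_perm permutations for the pairwise comparator.
#' @param seed RNG seed.
#' @return data.frame: `method`, `r`, `power`, `mc_se`, `n`, `n_replicates`.
#' @export
run_power_experiment <- function(pool1, pool2, n = 2000, K = 2,
                                 model = "dom_or_dom",
                                 r_grid = seq(0.1, 0.5, by = 0.1),
                                 methods = c("mfrg", "sfrg", "pca"),
                                 n_replicates = 200, alpha = 0.05,
                                 causal_fraction = 0.2,
                                 fpca = fpca_control(), rho = 0.5,
                                 n_perm = 200, seed = 1) {
  methods <- match.arg(methods, c("mfrg", "sfrg", "pca", "pairwise"),
                       several.ok = TRUE)
  set.seed(seed)
  causal1 <- select_causal(pool1, causal_fraction)
  causal2 <- select_causal(pool2, causal_fraction)
  grid_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                  length(r_grid) * n_replicates),
                       length(r_grid), n_replicates)
  res <- list()
  for (gi in seq_along(r_grid)) {
    r <- r_grid[gi]
    hits <- matrix(0, n_replicates, length(methods),
                   dimnames = list(NULL, methods))
    for (b in seq_len(n_replicates)) {
      set.seed(grid_seeds[gi, b])
      g1 <- sample_genotypes(pool1, n, region_id = "gene1")
      g2 <- sample_genotypes(pool2, n, region_id = "gene2")
      Y <- simulate_power_traits(g1, g2, causal1, causal2,
                                 model = model, r = r, K = K, rho = rho)
      for (m in methods) {
        p <- muffle_rank_warnings(switch(m,
          mfrg = test_gene_pair(g1, g2, Y, cfg = fpca)$p.value,
          sfrg = single_trait_frg(g1, g2, Y[, 1], cfg = fpca)$p.value,
          pca  = pca_interaction_test(g1, g2, Y)$p.value,
          pairwise = pairwise_max_test(g1, g2, Y, n_perm = n_perm,
                                       seed = grid_seeds[gi, b])$p_adjusted))
        hits[b, m] <- as.numeric(!is.na(p) && p <= alpha)
      }
    }
    pw <- colMeans(hits)
    res[[gi]] <- data.frame(method = methods, r = r, power = as.numeric(pw),
                            mc_se = sqrt(pw * (1 - pw) / n_replicates),
                            n = n, n_replicates = n_replicates)
  }
  do.call(rbind, res)
}
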