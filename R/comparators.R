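#' Single-trait functional regression interaction test
#'
#' The K = 1 special case of [mfrg()]: the Wald (or LRT) statistic reduces
#' to the classical single-response form with df = J*L.
#'
#' @param region1,region2 [genotype_region()] objects.
#' @param y single trait vector.
#' @param covariates optional covariate matrix.
#' @param cfg an [fpca_control()].
#' @param method `"wald"` or `"lrt"`.
#' @return An `mfrg_test`.
#' @export
single_trait_frg <- function(region1, region2, y, covariates = NULL,
                             cfg = fpca_control(),
                             method = c("wald", "lrt")) {
  test_gene_pair(region1, region2, matrix(as.numeric(y), ncol = 1),
                 covariates, cfg, match.arg(method))
}

#' Multi-trait interaction test on ordinary principal components
#'
#' The PCA comparator: per-gene principal component scores of the raw
#' (centered, unweighted) dosage matrix replace the functional scores, with
#' enough components per gene to explain `variance_threshold` (default 80%)
#' of the genetic variation; the multivariate Wald test of the interaction
#' block is then identical to the functional path.
#'
#' @param region1,region2 [genotype_region()] objects.
#' @param Y n x K trait matrix.
#' @param covariates optional covariate matrix.
#' @param variance_threshold per-gene variance fraction for component
#'   retention.
#' @param max_components cap on components per gene.
#' @return list of class `pca_comparator` with `k1`, `k2`, `statistic`,
#'   `df`, `p.value` (and the underlying `mfrg_test` as `$test`).
#' @export
pca_interaction_test <- function(region1, region2, Y, covariates = NULL,
                                 variance_threshold = 0.8,
                                 max_components = 10) {
  pc_scores <- function(region) {
    X <- region$dosage
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc / sqrt(nrow(Xc)), nu = 0)
    lambda <- sv$d^2
    keep <- lambda > max(lambda) * 1e-12
    lambda <- lambda[keep]
    cum <- cumsum(lambda) / sum(lambda)
    k <- min(which(cum >= variance_threshold - 1e-12)[1], max_components,
             length(lambda))
    list(scores = Xc %*% sv$v[, seq_len(k), drop = FALSE], k = k)
  }
  p1 <- pc_scores(region1)
  p2 <- pc_scores(region2)
  design <- build_design(p1$scores, p2$scores, covariates)
  t <- wald_test(mfrg_fit(design, as.matrix(Y)))
  structure(list(k1 = p1$k, k2 = p2$k, statistic = t$statistic,
                 df = t$df, p.value = t$p.value, test = t),
            class = "pca_comparator")
}

#' @export
print.pca_comparator <- function(x, ...) {
  cat(sprintf("PC-regression interaction test: k1 = %d, k2 = %d, statistic = %.4g, df = %d, p = %.4g\n",
              x$k1, x$k2, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Permutation-adjusted maximum pairwise SNP interaction test
#'
#' The traditional point-wise comparator: for every SNP pair (one from each
#' gene) and every trait, the squared Wald t statistic of the product term
#' in `y = mu + x1 a1 + x2 a2 + x1 x2 g + e` is computed; the observed
#' maximum over all pairs and traits is compared with its permutation null,
#' obtained by jointly permuting the phenotype rows (all traits together, so
#' trait correlation is preserved).  Pairs whose product column is constant
#' (e.g. no double carriers of two rare alleles) are skipped.
#'
#' @param region1,region2 [genotype_region()] objects.
#' @param Y n x K trait matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return list of class `pairwise_scan`: `table` (SNP1, SNP2, trait,
#'   statistic), `T_max`, `p_adjusted = (1 + #{perm >= obs}) / (n_perm +
#'   1)`, `n_perm`, `skipped` (count of skipped pairs).
#' @export
pairwise_max_test <- function(region1, region2, Y, n_perm = 1000,
                              seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  n <- nrow(Y); M <- ncol(Y)
  G1 <- region1$dosage; G2 <- region2$dosage
  k1 <- ncol(G1); k2 <- ncol(G2)
  # product columns and per-pair design cross-products, precomputed once
  P <- matrix(0, n, k1 * k2)
  idx <- 1
  pair_id <- matrix(0L, k1 * k2, 2)
  for (j in seq_len(k1)) for (l in seq_len(k2)) {
    P[, idx] <- G1[, j] * G2[, l]
    pair_id[idx, ] <- c(j, l)
    idx <- idx + 1
  }
  ok <- logical(k1 * k2)
  XtX_inv <- vector("list", k1 * k2)
  for (m in seq_len(k1 * k2)) {
    X <- cbind(1, G1[, pair_id[m, 1]], G2[, pair_id[m, 2]], P[, m])
    XtX <- crossprod(X)
    # skip degenerate pairs (constant product column / collinear design)
    if (rcond_sym(XtX) > 1e-12 && stats::var(P[, m]) > 0) {
      ok[m] <- TRUE
      XtX_inv[[m]] <- chol2inv(chol(XtX))
    }
  }
  if (!any(ok))
    stop_mfrg("all SNP pairs degenerate (no informative product columns)",
              "mfrg_undefined_test")
  # statistics for one response matrix (columns = traits or permutations)
  # using only cross-products X'y per pair
  stat_block <- function(Ymat) {
    yty <- colSums(Ymat^2)
    C1 <- crossprod(G1, Ymat)   # k1 x B
    C2 <- crossprod(G2, Ymat)   # k2 x B
    CP <- crossprod(P, Ymat)    # (k1 k2) x B
    C0 <- colSums(Ymat)
    out <- matrix(NA_real_, sum(ok), ncol(Ymat))
    row <- 1
    for (m in which(ok)) {
      Xty <- rbind(C0, C1[pair_id[m, 1], ], C2[pair_id[m, 2], ], CP[m, ])
      B <- XtX_inv[[m]] %*% Xty           # 4 x B coefficients
      rss <- yty - colSums(B * Xty)
      sigma2 <- rss / (n - 4)
      out[row, ] <- B[4, ]^2 / (sigma2 * XtX_inv[[m]][4, 4])
      row <- row + 1
    }
    out
  }
  obs <- stat_block(Y)
  T_max <- max(obs)
  perms <- replicate(n_perm, sample.int(n))
  exceed <- 0L
  # permute in blocks of columns to keep one BLAS call per trait
  for (m in seq_len(M)) {
    Yp <- matrix(Y[perms, m], n, n_perm)
    pm <- stat_block(Yp)
    if (m == 1) perm_max <- apply(pm, 2, max) else
      perm_max <- pmax(perm_max, apply(pm, 2, max))
  }
  exceed <- sum(perm_max >= T_max)
  tab <- data.frame(
    snp1 = rep(pair_id[ok, 1], times = M),
    snp2 = rep(pair_id[ok, 2], times = M),
    trait = rep(seq_len(M), each = sum(ok)),
    statistic = as.numeric(obs))
  structure(list(table = tab, T_max = T_max,
                 p_adjusted = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, skipped = sum(!ok)),
            class = "pairwise_scan")
}

#' @export
print.pairwise_scan <- function(x, ...) {
  cat(sprintf("pairwise max interaction test: T_max = %.4g, adjusted p = %.4g (%d permutations, %d pairs skipped)\n",
              x$T_max, x$p_adjusted, x$n_perm, x$skipped))
  invisible(x)
}

# cheap symmetric reciprocal condition estimate
rcond_sym <- function(M) {
  d <- tryCatch(range(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                error = function(e) c(0, 1))
  if (d[2] <= 0) return(0)
  max(d[1], 0) / d[2]
}
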