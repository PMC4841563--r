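#' Bonferroni threshold for a gene-pair scan
#'
#' `alpha_family / choose(n_genes, 2)` when a gene count is given, or
#' `alpha_family / n_pairs` when an explicit pair count is given.
#'
#' @param n_genes number of genes in an all-pairs scan (>= 2).
#' @param n_pairs explicit number of tested pairs (overrides `n_genes`).
#' @param alpha_family family-wise error rate (default 0.05).
#' @return per-test significance threshold.
#' @examples
#' bonferroni_threshold(n_genes = 18587)   # 2.89e-10
#' @export
bonferroni_threshold <- function(n_genes = NULL, n_pairs = NULL,
                                 alpha_family = 0.05) {
  if (!is.null(n_pairs)) {
    if (n_pairs < 1) stop_mfrg("n_pairs must be positive", "mfrg_bad_input")
    return(alpha_family / n_pairs)
  }
  if (is.null(n_genes) || n_genes < 2)
    stop_mfrg("need at least 2 genes", "mfrg_bad_input")
  alpha_family / choose(n_genes, 2)
}

#' QQ table of observed versus expected -log10 p-values
#'
#' Expected order statistics for m tests are `-log10((i - 0.5) / m)`.
#'
#' @param p vector of p-values.
#' @return data.frame with `expected` and `observed` columns, sorted by
#'   significance.
#' @export
qq_points <- function(p) {
  p <- p[!is.na(p)]
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p)))
}

#' Interaction network edge list with per-gene degrees
#'
#' Filters scan results to pairs passing a significance threshold and
#' summarizes per-gene degree (hub genes are the max-degree nodes).
#'
#' @param results data.frame with columns `gene1`, `gene2`, `p`.
#' @param threshold per-pair significance threshold.
#' @return list: `edges` (gene1, gene2, p), `degrees` (gene, degree, sorted
#'   decreasing), `hub` (max-degree gene).
#' @export
interaction_network <- function(results, threshold) {
  stopifnot(all(c("gene1", "gene2", "p") %in% names(results)))
  edges <- results[!is.na(results$p) & results$p <= threshold,
                   c("gene1", "gene2", "p"), drop = FALSE]
  if (nrow(edges)) {
    deg <- sort(table(c(edges$gene1, edges$gene2)), decreasing = TRUE)
    degrees <- data.frame(gene = names(deg), degree = as.integer(deg))
    hub <- degrees$gene[1]
  } else {
    degrees <- data.frame(gene = character(0), degree = integer(0))
    hub <- NA_character_
  }
  list(edges = edges, degrees = degrees, hub = hub)
}

#' Ancestry principal components from a genome-wide dosage sample
#'
#' Top principal components of the column-standardized dosage matrix,
#' returned as covariate columns for population-stratification adjustment
#' (five PCs is the conventional choice).
#'
#' @param dosage n x m genome-wide dosage matrix (m well beyond `n_pcs`).
#' @param n_pcs number of components (0 returns a zero-column matrix).
#' @return n x `n_pcs` matrix of orthogonal PC scores.
#' @export
ancestry_pcs <- function(dosage, n_pcs = 5) {
  dosage <- as.matrix(dosage)
  if (n_pcs == 0) return(matrix(0, nrow(dosage), 0))
  Xc <- sweep(dosage, 2, colMeans(dosage))
  sdv <- apply(dosage, 2, stats::sd)
  keep <- sdv > 0
  Xc <- sweep(Xc[, keep, drop = FALSE], 2, sdv[keep], "/")
  sv <- svd(Xc, nu = min(n_pcs, min(dim(Xc))), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  k <- min(n_pcs, rank)
  if (k < n_pcs)
    warning(sprintf("dosage matrix supports only %d PCs (requested %d)",
                    k, n_pcs))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Gene-pair interaction scan
#'
#' Runs the interaction test over a list of gene pairs (or all pairs of the
#' supplied regions), applying the rank-based inverse normal transform to
#' each trait, adjusting for covariates, skipping genes that cannot support
#' the functional expansion, and returning per-pair results together with a
#' QQ table, the Bonferroni threshold for the realized number of tests, and
#' the significant-interaction network.
#'
#' @param regions named list of [genotype_region()] objects on a common
#'   sample set (e.g. from [read_region()] over [read_gene_windows()]).
#' @param Y n x K trait matrix.
#' @param covariates optional covariate matrix.
#' @param pairs two-column matrix/data.frame of gene names; `NULL` tests all
#'   pairs.
#' @param method `"wald"` or `"lrt"`.
#' @param fpca an [fpca_control()].
#' @param transform inverse-normal-transform the traits (default TRUE).
#' @param alpha_family family-wise error rate for the network threshold.
#' @param output_prefix if non-`NULL`, write `<prefix>_results.tsv`,
#'   `<prefix>_qq.tsv` and `<prefix>_edges.tsv`.
#' @return list of class `mfrg_scan`: `results` (gene1, gene2, chrom1,
#'   chrom2, J, L, K, statistic, df, p), `skipped` (gene, reason),
#'   `threshold`, `qq`, `network`.
#' @export
run_scan <- function(regions, Y, covariates = NULL, pairs = NULL,
                     method = c("wald", "lrt"), fpca = fpca_control(),
                     transform = TRUE, alpha_family = 0.05,
                     output_prefix = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(regions), length(regions) >= 2)
  if (is.null(names(regions)))
    names(regions) <- vapply(regions, `[[`, character(1), "region_id")
  Y <- as.matrix(Y)
  if (transform) Y <- apply(Y, 2, inverse_normal_transform)
  # genes unable to support the expansion are skipped once, up front
  usable <- vapply(regions, function(r) ncol(r$dosage) >= 4, logical(1))
  skipped <- data.frame(gene = names(regions)[!usable],
                        reason = rep("fewer than 4 variants", sum(!usable)))
  if (is.null(pairs)) {
    nm <- names(regions)[usable]
    if (length(nm) < 2)
      stop_mfrg("fewer than 2 usable genes", "mfrg_bad_input")
    pairs <- t(utils::combn(nm, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    row <- data.frame(gene1 = g1, gene2 = g2,
                      chrom1 = regions[[g1]]$chrom,
                      chrom2 = regions[[g2]]$chrom,
                      J = NA_integer_, L = NA_integer_, K = ncol(Y),
                      statistic = NA_real_, df = NA_integer_, p = NA_real_,
                      note = "")
    t <- tryCatch(
      muffle_rank_warnings(
        test_gene_pair(regions[[g1]], regions[[g2]], Y, covariates,
                       cfg = fpca, method = method)),
      error = function(e) e)
    if (inherits(t, "error")) {
      row$note <- conditionMessage(t)
    } else {
      row$J <- t$J; row$L <- t$L
      row$statistic <- t$statistic; row$df <- t$df; row$p <- t$p.value
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  threshold <- bonferroni_threshold(n_pairs = nrow(results),
                                    alpha_family = alpha_family)
  qq <- qq_points(results$p)
  network <- interaction_network(results, threshold)
  out <- structure(list(results = results, skipped = skipped,
                        threshold = threshold, qq = qq, network = network),
                   class = "mfrg_scan")
  if (!is.null(output_prefix)) {
    utils::write.table(results, paste0(output_prefix, "_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qq, paste0(output_prefix, "_qq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(network$edges, paste0(output_prefix, "_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.mfrg_scan <- function(x, ...) {
  cat(sprintf("interaction scan: %d pairs tested, %d genes skipped, Bonferroni threshold %.3g\n",
              nrow(x$results), nrow(x$skipped), x$threshold))
  cat(sprintf("  %d pair(s) significant", nrow(x$network$edges)))
  if (nrow(x$network$edges))
    cat(sprintf("; hub gene: %s (degree %d)", x$network$hub,
                x$network$degrees$degree[1]))
  cat("\n")
  invisible(x)
}
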