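#' Control parameters for the functional expansion of genotype profiles
#'
#' Each individual's dosage profile across a region is treated as a function
#' of (rescaled) genomic position; profiles are optionally pre-smoothed onto
#' a small basis, then expanded in eigenfunctions of the empirical covariance
#' function.  The retained number of components J is the smallest number
#' whose cumulative variance reaches `variance_threshold`, capped at
#' `max_components`.
#'
#' The default is a small Fourier system (`n_smoothing_basis = 7`: constant
#' plus three harmonic pairs).  The method's premise is that only a few
#' eigenfunctions carry the region-wide genetic variation; projecting the raw
#' step-function profiles onto a low-order smooth basis before the
#' eigen-expansion enforces that and keeps the downstream degrees of freedom
#' K*J*L modest even for regions with many variants.  `smoothing = "none"`
#' performs the expansion on the raw discrete profiles (in which case, with
#' uniform quadrature weights, the expansion coincides with ordinary PCA of
#' the centered dosage matrix).
#'
#' @param smoothing `"fourier"`, `"bspline"` or `"none"`.
#' @param n_smoothing_basis number of basis functions (Fourier: odd).
#' @param variance_threshold fraction of variance the retained components
#'   must explain, in (0, 1].
#' @param max_components cap on the number of retained components.
#' @param quadrature `"trapezoid"` (integrals approximated by the trapezoid
#'   rule on the rescaled variant grid) or `"uniform"` (unit weights).
#' @return list of class `fpca_control`.
#' @export
fpca_control <- function(smoothing = c("fourier", "bspline", "none"),
                         n_smoothing_basis = 7,
                         variance_threshold = 0.8,
                         max_components = 10,
                         quadrature = c("trapezoid", "uniform")) {
  smoothing <- match.arg(smoothing)
  quadrature <- match.arg(quadrature)
  stopifnot(n_smoothing_basis >= 1, variance_threshold > 0,
            variance_threshold <= 1, max_components >= 1)
  structure(list(smoothing = smoothing,
                 n_smoothing_basis = as.integer(n_smoothing_basis),
                 variance_threshold = variance_threshold,
                 max_components = as.integer(max_components),
                 quadrature = quadrature),
            class = "fpca_control")
}

#' Rescale genomic positions to the unit interval
#'
#' Affine map `t -> (t - a) / (b - a)` of positions inside the region
#' `[a, b]`; already-rescaled grids (a = 0, b = 1) are left unchanged.
#'
#' @param positions strictly increasing positions within `[a, b]`.
#' @param a,b region bounds; default the range of `positions`.
#' @export
rescale_positions <- function(positions, a = min(positions),
                              b = max(positions)) {
  if (a == b) stop_mfrg("degenerate region: a == b", "mfrg_degenerate_region")
  if (any(positions < a | positions > b))
    stop_mfrg("positions outside [a, b]", "mfrg_bad_input")
  (positions - a) / (b - a)
}

# trapezoid quadrature weights on a grid in [0, 1]
trapezoid_weights <- function(grid) {
  p <- length(grid)
  if (p == 1) return(1)
  d <- diff(grid)
  c(d[1] / 2, (d[-1] + d[-(p - 1)]) / 2, d[p - 1] / 2)
}

# basis matrix (n_gridpoints x n_basis) evaluated on grid in [0,1]
smoothing_basis <- function(grid, kind, nb) {
  p <- length(grid)
  nb <- min(nb, p)
  if (kind == "fourier") {
    if (nb %% 2 == 0) nb <- nb - 1L   # constant + sine/cosine pairs
    H <- matrix(1, p, nb)
    k <- 1
    j <- 2
    while (j <= nb) {
      H[, j] <- sin(2 * pi * k * grid)
      if (j + 1 <= nb) H[, j + 1] <- cos(2 * pi * k * grid)
      j <- j + 2; k <- k + 1
    }
    H
  } else {
    df <- max(nb, 4)  # cubic B-splines need >= 4 dof
    splines::bs(grid, df = min(df, p), intercept = TRUE)
  }
}

#' Functional principal component expansion of a genotype region
#'
#' Centers the dosage columns, optionally smooths each profile onto a small
#' basis, and diagonalizes the quadrature-weighted empirical covariance
#' function.  Scores are the quadrature inner products of each centered
#' (smoothed) profile with the orthonormal eigenfunctions, i.e. the
#' coefficients of the truncated eigen-expansion of the genotype function.
#'
#' @param region a [genotype_region()] with at least 4 variants and no
#'   missing dosages.
#' @param cfg an [fpca_control()].
#' @return Object of class `fpca_scores` with fields `scores`
#'   (n x J), `eigenvalues` (all positive eigenvalues), `basis_values`
#'   (J x n_gridpoints eigenfunctions), `grid`, `weights`, `center`
#'   (training column means), `variance_explained` (cumulative fractions of
#'   the retained components), `n_components`, and `smoother` (the implied
#'   linear pre-smoothing map, for projecting new profiles).
#' @export
fit_fpca <- function(region, cfg = fpca_control()) {
  stopifnot(inherits(region, "genotype_region"))
  check_region_size(region)
  X <- region$dosage
  if (anyNA(X)) stop_mfrg("missing dosages: impute or drop first",
                          "mfrg_bad_input")
  pos <- region$positions
  # deterministic jitter of duplicated positions (one grid step of 1 bp)
  while (any(duplicated(pos))) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1
  grid <- rescale_positions(pos)
  n <- nrow(X); p <- ncol(X)
  w <- if (cfg$quadrature == "trapezoid") trapezoid_weights(grid) else
    rep(1, p)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (all(abs(Xc) < 1e-14))
    stop_mfrg("region has zero genotypic variance", "mfrg_degenerate_region")
  if (cfg$smoothing == "none") {
    S <- diag(p)
  } else {
    H <- smoothing_basis(grid, cfg$smoothing, cfg$n_smoothing_basis)
    # weighted least-squares smoother: x -> H (H' W H)^-1 H' W x
    HW <- H * w
    G <- crossprod(H, HW)
    S <- H %*% solve(G + diag(1e-10, ncol(H)), t(HW))
  }
  Xs <- Xc %*% t(S)                       # smoothed profiles on the grid
  Z <- Xs * rep(sqrt(w), each = n)
  sv <- svd(Z / sqrt(n), nu = 0)
  pos_ev <- sv$d^2 > max(sv$d^2) * 1e-12
  lambda <- sv$d[pos_ev]^2
  V <- sv$v[, pos_ev, drop = FALSE]
  phi <- V / sqrt(w)                      # orthonormal wrt quadrature rule
  # sign convention: largest-magnitude grid value positive
  for (j in seq_len(ncol(phi))) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) { phi[, j] <- -phi[, j]; V[, j] <- -V[, j] }
  }
  cum <- cumsum(lambda) / sum(lambda)
  J <- min(which(cum >= cfg$variance_threshold - 1e-12)[1],
           cfg$max_components, length(lambda))
  scores <- Xs %*% (phi[, seq_len(J), drop = FALSE] * w)
  colnames(scores) <- paste0("fpc", seq_len(J))
  structure(
    list(scores = scores,
         eigenvalues = lambda,
         basis_values = t(phi[, seq_len(J), drop = FALSE]),
         grid = grid,
         weights = w,
         center = center,
         smoother = S,
         variance_explained = cum[seq_len(J)],
         n_components = J,
         region_id = region$region_id),
    class = "fpca_scores")
}

#' @export
print.fpca_scores <- function(x, ...) {
  cat(sprintf("fpca_scores '%s': %d components, %.1f%% variance explained\n",
              x$region_id, x$n_components,
              100 * x$variance_explained[x$n_components]))
  invisible(x)
}

#' Project genotype profiles onto a fitted eigenfunction basis
#'
#' Centers new profiles with the training means, applies the training
#' smoother, and takes quadrature inner products with the stored
#' eigenfunctions.  Projecting the training region reproduces its scores.
#'
#' @param region a [genotype_region()] observed on the same variant grid.
#' @param fit an `fpca_scores` object from [fit_fpca()].
#' @return n x J score matrix.
#' @export
project_profiles <- function(region, fit) {
  stopifnot(inherits(fit, "fpca_scores"))
  X <- if (inherits(region, "genotype_region")) region$dosage else
    as.matrix(region)
  if (ncol(X) != length(fit$grid))
    stop_mfrg("variant grid mismatch between region and basis", "mfrg_bad_input")
  Xc <- sweep(X, 2, fit$center)
  Xs <- Xc %*% t(fit$smoother)
  Xs %*% (t(fit$basis_values) * fit$weights)
}
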