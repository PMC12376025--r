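## Reference data-driven classifier: derivative Laplacian similarity plus
## spectral clustering with a fixed cluster count.

#' Interpolate curves onto a shared log-spaced grid
#'
#' Log10 intensity is interpolated onto a common log-spaced q grid over
#' the intersection of all curve ranges, and each row is standardized to
#' zero mean and unit variance (so overall intensity scaling becomes an
#' offset in log space and is removed).  Non-positive intensities are
#' clipped to a small positive floor before taking logs (and logged).
#'
#' @param curves list of [sas_curve] objects.
#' @param n_grid number of grid points.
#' @param floor positive clip value for non-positive intensities.
#' @return A `curve_matrix`: list with `common_q`, `rows` (matrix, one
#'   standardized log-intensity row per curve) and `meta` (sample ids).
#' @export
preprocess_curves <- function(curves, n_grid = 128L, floor = 1e-12) {
  stopifnot(length(curves) >= 1L)
  qlo <- max(vapply(curves, function(cv) min(cv$q), 0))
  qhi <- min(vapply(curves, function(cv) max(cv$q), 0))
  if (qlo >= qhi) domain_error("curves have no common q range")
  grid <- exp(seq(log(qlo), log(qhi), length.out = n_grid))
  rows <- t(vapply(curves, function(cv) {
    I <- cv$intensity
    n_clip <- sum(I <= 0)
    if (n_clip > 0) {
      log_event(sprintf("[%s] clipped %d non-positive intensities before log",
                        cv$sample_id, n_clip))
      I <- pmax(I, floor)
    }
    y <- stats::approx(log(cv$q), log10(I), xout = log(grid), rule = 2)$y
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) s <- 1
    (y - mean(y)) / s
  }, numeric(n_grid)))
  structure(list(common_q = grid, rows = rows,
                 meta = vapply(curves, `[[`, "", "sample_id")),
            class = "curve_matrix")
}

#' Savitzky-Golay derivative stack
#'
#' Returns the 0th, 1st and 2nd order derivatives of each preprocessed
#' row with respect to log q, using a Savitzky-Golay filter (window 11,
#' polynomial order 3).  Order 0 is the input itself.
#'
#' @param m a `curve_matrix` from [preprocess_curves].
#' @param window filter window length (odd).
#' @param poly_order filter polynomial order.
#' @return List of three matrices (orders 0, 1, 2).
#' @export
derivative_stack <- function(m, window = 11L, poly_order = 3L) {
  stopifnot(inherits(m, "curve_matrix"))
  ng <- ncol(m$rows)
  if (ng < window)
    config_error(sprintf("grid length %d shorter than SG window %d", ng, window))
  h <- diff(log10(m$common_q))[1]
  d1 <- t(apply(m$rows, 1, function(y)
    signal::sgolayfilt(y, p = poly_order, n = window, m = 1, ts = h)))
  d2 <- t(apply(m$rows, 1, function(y)
    signal::sgolayfilt(y, p = poly_order, n = window, m = 2, ts = h)))
  list(m$rows, d1, d2)
}

#' Combined Laplacian similarity across derivative orders
#'
#' For each derivative order, pairwise Euclidean distances `d` become a
#' Gaussian affinity `W = exp(-d^2 / (2 eps^2))` with `eps` the median
#' nonzero distance (when `kernel_scale = "auto"`); the combined
#' affinity is the elementwise geometric mean over the three orders.
#' The result is symmetric with unit diagonal and entries in (0, 1].
#'
#' @param stacks list of matrices from [derivative_stack].
#' @param kernel_scale positive bandwidth, or `"auto"` for the median
#'   heuristic.
#' @return Affinity matrix.
#' @export
laplacian_similarity <- function(stacks, kernel_scale = "auto") {
  if (!identical(kernel_scale, "auto") &&
      (!is.numeric(kernel_scale) || kernel_scale <= 0))
    config_error("kernel_scale must be positive or 'auto'")
  logW <- 0
  for (s in stacks) {
    d <- as.matrix(stats::dist(s))
    eps <- if (identical(kernel_scale, "auto")) {
      nz <- d[upper.tri(d)]
      nz <- nz[nz > 0]
      if (length(nz) == 0) 1 else stats::median(nz)
    } else kernel_scale
    logW <- logW + (-d^2 / (2 * eps^2))
  }
  W <- exp(logW / length(stacks))
  diag(W) <- 1
  W
}

#' Spectral clustering of an affinity matrix
#'
#' Builds the symmetric-normalized graph Laplacian
#' `L = I - D^(-1/2) W D^(-1/2)`, takes the eigenvectors of its `k`
#' smallest eigenvalues, row-normalizes them, and clusters the embedded
#' points with seeded k-means (20 restarts).  Deterministic for a fixed
#' seed.
#'
#' @param W symmetric affinity matrix with positive degrees.
#' @param k number of clusters, `<=` number of curves.
#' @param seed integer seed for the k-means restarts.
#' @param names optional sample names used in error messages.
#' @return Integer cluster labels in `0..k-1`.
#' @export
spectral_cluster <- function(W, k, seed = 1L, names = NULL) {
  n <- nrow(W)
  stopifnot(k >= 1L, k <= n)
  deg <- rowSums(W)
  if (any(deg <= 0)) {
    bad <- which(deg <= 0)[1]
    domain_error(sprintf("zero-degree node in affinity graph: curve %s",
                         if (is.null(names)) bad else names[bad]))
  }
  if (k == n) return(seq_len(n) - 1L)  # every curve its own cluster
  dm <- 1 / sqrt(deg)
  L <- diag(n) - (dm * W) %*% diag(dm)  # D^-1/2 W D^-1/2 via row/col scaling
  L <- (L + t(L)) / 2
  ee <- eigen(L, symmetric = TRUE)
  U <- ee$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, stats::kmeans(U, centers = k, nstart = 20L,
                                      iter.max = 100L))
  as.integer(km$cluster - 1L)
}

#' Derivative-similarity spectral classification of curves
#'
#' The full reference pipeline: [preprocess_curves],
#' [derivative_stack], [laplacian_similarity], [spectral_cluster].
#'
#' @param curves list of [sas_curve] objects.
#' @param k fixed cluster count (prior knowledge of the phase number).
#' @param seed k-means seed.
#' @param n_grid interpolation grid size.
#' @return Data frame with `sample_id` and integer `cluster` (0-based).
#' @export
classify_curves_ml <- function(curves, k = 3L, seed = 1L, n_grid = 128L) {
  m <- preprocess_curves(curves, n_grid)
  W <- laplacian_similarity(derivative_stack(m))
  labels <- spectral_cluster(W, k, seed, names = m$meta)
  data.frame(sample_id = m$meta, cluster = labels)
}
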