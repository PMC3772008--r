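.asDistMatrix <- function(d) {
  if (is(d, "LaneDistanceMatrix")) return(distValues(d))
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("L", seq_len(nrow(m)))
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-9) || any(diag(m) != 0))
    stop("distance input must be symmetric with a zero diagonal")
  m
}

#' Classical (Torgerson) multidimensional scaling of lane distances
#'
#' Double-centers the squared distances and embeds the lanes on the top-k
#' non-negative eigenpairs (via [stats::cmdscale()]). If fewer than k
#' positive eigenvalues exist, the embedding is truncated with a warning.
#' The share of negative eigenvalue mass — how non-Euclidean the input is —
#' is retained in the eigenvalue spectrum.
#'
#' @param d a [LaneDistanceMatrix-class], `dist`, or symmetric matrix.
#' @param k target dimension (default 2).
#' @return an [OrdinationResult-class] with centered coordinates and the
#'   eigenvalue spectrum; `ordStress()` is NA for classical MDS.
#' @export
classicalMDS <- function(d, k = 2L) {
  m <- .asDistMatrix(d)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- nrow(m)
  if (k > n - 1L) k <- n - 1L
  fit <- suppressWarnings(stats::cmdscale(m, k = k, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > max(eig, 0) * 1e-12)
  pts <- fit$points
  if (npos < k) {
    warning("only ", npos, " positive eigenvalue(s); embedding truncated")
    if (npos == 0L) pts <- matrix(0, n, 1L)
    else pts <- pts[, seq_len(min(npos, ncol(pts))), drop = FALSE]
  }
  pts <- scale(pts, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- NULL
  new("OrdinationResult", laneIds = rownames(m), points = pts,
      stress = NA_real_, eigenvalues = sort(eig, decreasing = TRUE),
      method = "classical", converged = TRUE)
}

#' Non-metric multidimensional scaling of lane distances
#'
#' Minimizes Kruskal stress-1, sqrt(sum (dhat_ij - delta_ij)^2 /
#' sum delta_ij^2), by iterative majorization with monotone (isotonic)
#' regression of the fitted disparities on the rank order of the input
#' distances, starting from the classical-MDS configuration. The
#' optimization is delegated to [vegan::monoMDS()] (global model, primary
#' tie treatment), which implements exactly this criterion and handles tied
#' and zero dissimilarities. Deterministic: the start is the classical
#' embedding, so the same input always gives the same output; `seed` is
#' accepted for interface uniformity with the stochastic stages.
#'
#' @inheritParams classicalMDS
#' @param seed unused by the deterministic optimizer; kept so pipeline
#'   configs can set every stage's seed uniformly.
#' @param maxIter maximum iterations (default 300).
#' @param tol relative stress-change convergence tolerance (default 1e-6).
#' @return an [OrdinationResult-class]; `ordStress()` is the final Kruskal
#'   stress-1 and `@converged` records whether the tolerance was reached
#'   before `maxIter`.
#' @export
nonmetricMDS <- function(d, k = 2L, seed = NULL, maxIter = 300L,
                         tol = 1e-6) {
  m <- .asDistMatrix(d)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  init <- classicalMDS(m, k)
  y <- ordPoints(init)
  if (ncol(y) < k)  # degenerate input; pad so monoMDS gets k columns
    y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  fit <- vegan::monoMDS(stats::as.dist(m), y = y, k = k, model = "global",
                        maxit = as.integer(maxIter), sfgrmin = 1e-7,
                        sratmax = 1 - tol)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- NULL
  new("OrdinationResult", laneIds = rownames(m), points = pts,
      stress = fit$stress, eigenvalues = numeric(0), method = "nonmetric",
      converged = fit$icause != 1L)
}

#' Write ordination coordinates as CSV
#'
#' @param object an [OrdinationResult-class].
#' @param path CSV path; columns `lane_id`, `x`, `y`, ...
#' @return the path, invisibly.
#' @export
writeOrdination <- function(object, path) {
  stopifnot(is(object, "OrdinationResult"))
  p <- ordPoints(object)
  nm <- paste0("dim", seq_len(ncol(p)))
  nm[seq_len(min(2L, ncol(p)))] <- c("x", "y")[seq_len(min(2L, ncol(p)))]
  colnames(p) <- nm
  utils::write.csv(data.frame(lane_id = laneIds(object), p,
                              row.names = NULL), path, row.names = FALSE)
  invisible(path)
}
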