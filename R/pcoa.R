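#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of \eqn{-D^2/2},
#' eigendecomposition, and coordinates scaled by the square root of the
#' eigenvalues. Axes are ordered by decreasing eigenvalue; negative
#' eigenvalues (non-embeddable part of the matrix) are reported but
#' excluded from the percent-variance denominator.
#'
#' @param d symmetric distance matrix with zero diagonal (e.g. a pairwise
#'   F_ST matrix; slightly negative entries are clamped to zero for the
#'   embedding).
#' @param axes maximum number of axes to return.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (populations x axes), `eigenvalues` (all of them, decreasing), and
#'   `percent_variance` (per returned axis, over positive eigenvalues).
#' @export
pcoa_coords <- function(d, axes = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-12)) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  n <- nrow(d)
  if (is.null(axes)) axes <- n - 1
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(pmax(d, 0)), k = min(axes, n - 1),
                    eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12]
  pts <- fit$points
  if (NCOL(pts) == 0) {
    pts <- matrix(0, n, 0)
    rownames(pts) <- rownames(d)
  }
  keep <- seq_len(min(ncol(pts), length(pos), axes))
  pts <- pts[, keep, drop = FALSE]
  colnames(pts) <- paste0("Axis", keep)
  if (!is.null(rownames(d))) rownames(pts) <- rownames(d)
  structure(
    list(coordinates = pts,
         eigenvalues = eig,
         percent_variance = if (length(pos)) 100 * pos[keep] / sum(pos)
         else numeric(0)),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d axes (%s%% of positive-eigenvalue variance)\n",
              ncol(x$coordinates),
              paste(sprintf("%.1f", x$percent_variance), collapse = " + ")))
  print(round(x$coordinates, 5))
  invisible(x)
}
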