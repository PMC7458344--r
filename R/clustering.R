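#' Iterative SVD imputation of missing entries
#'
#' Fills missing entries by iterating a truncated singular value
#' decomposition: missing cells are initialized to their row means, the
#' matrix is approximated at the given rank, and the missing cells are
#' replaced by the reconstruction until the largest absolute change in any
#' imputed entry falls below `tol` or `max_iter` is reached. Observed
#' entries are never altered.
#'
#' @param mat Numeric matrix, possibly with `NA` entries. Every row and
#'   column must have at least one observed value.
#' @param rank Truncation rank; default `min(dim(mat)) - 1` capped at 10.
#' @param tol Convergence tolerance on imputed entries (default `1e-6`).
#' @param max_iter Iteration cap (default 100); non-convergence returns the
#'   current estimate with a warning and `converged = FALSE` attribute.
#' @return The completed matrix, with attributes `converged` (logical) and
#'   `iterations`.
#' @export
svd_impute <- function(mat, rank = NULL, tol = 1e-6, max_iter = 100L) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  miss <- is.na(mat)
  if (!any(miss)) {
    return(structure(mat, converged = TRUE, iterations = 0L))
  }
  if (any(rowSums(!miss) == 0L)) stop("row with no observed entries")
  if (any(colSums(!miss) == 0L)) stop("column with no observed entries")
  if (is.null(rank)) rank <- min(min(dim(mat)) - 1L, 10L)
  if (rank < 1L || rank >= min(dim(mat))) {
    stop("rank must satisfy 1 <= rank < min(dim)")
  }
  filled <- mat
  rm_ <- rowMeans(mat, na.rm = TRUE)
  filled[miss] <- rm_[row(mat)[miss]]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- svd(filled, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("SVD imputation did not converge in ", max_iter, " iterations")
  structure(filled, converged = converged, iterations = iter)
}

#' Row scaling for clustering and PCA
#'
#' @param mat Numeric matrix.
#' @param mode `"none"`, `"center"` (subtract row means) or
#'   `"unit_variance"` (center, then divide by row standard deviation).
#' @return Scaled matrix.
#' @export
scale_rows <- function(mat, mode = c("none", "center", "unit_variance")) {
  mode <- match.arg(mode)
  if (mode == "none") return(mat)
  ctr <- sweep(mat, 1L, rowMeans(mat, na.rm = TRUE))
  if (mode == "center") return(ctr)
  sds <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  zero <- which(sds == 0)
  if (length(zero) > 0L) {
    stop("zero-variance row(s) under unit_variance scaling: ",
         paste(if (is.null(rownames(mat))) zero else rownames(mat)[zero],
               collapse = ", "))
  }
  sweep(ctr, 1L, sds, `/`)
}

#' Hierarchical clustering with the conventions used for infiltrate heatmaps
#'
#' Agglomerative clustering of matrix rows under Euclidean, Manhattan or
#' correlation distance (1 - Pearson r across the features) with complete or
#' average linkage, cut into `k` groups. To cluster samples instead, pass
#' the transposed matrix.
#'
#' @param mat Numeric matrix; rows are the items clustered.
#' @param distance `"euclidean"`, `"manhattan"` or `"correlation"`.
#' @param linkage `"complete"` or `"average"`.
#' @param row_scaling Scaling applied first, see [scale_rows()].
#' @param k Number of clusters to cut (default 2).
#' @return List with `hclust` (the merge tree), `labels` (named integer
#'   cluster assignment) and `distance`/`linkage` echoes.
#' @export
hcluster <- function(mat, distance = c("euclidean", "manhattan", "correlation"),
                     linkage = c("complete", "average"),
                     row_scaling = c("none", "center", "unit_variance"),
                     k = 2L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  row_scaling <- match.arg(row_scaling)
  if (nrow(mat) < 2L) stop("need at least 2 items to cluster")
  mat <- scale_rows(mat, row_scaling)
  if (distance == "correlation") {
    if (ncol(mat) < 2L) stop("correlation distance needs >= 2 features per item")
    sds <- apply(mat, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant item(s) under correlation distance: ",
           paste(rownames(mat)[which(sds == 0)], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(mat)))
  } else {
    d <- stats::dist(mat, method = distance)
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, labels = stats::cutree(hc, k = k),
       distance = distance, linkage = linkage)
}

#' Serialize a clustering tree as Newick
#'
#' @param hc An `hclust` object (e.g. `hcluster(...)$hclust`).
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly if written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Principal component analysis with SVD imputation
#'
#' Samples (columns) are projected onto principal components of the
#' variables-in-rows matrix after optional row scaling; missing values are
#' completed with [svd_impute()] first.
#'
#' @param mat Numeric matrix, variables in rows, samples in columns.
#' @param row_scaling Scaling applied to rows first (default
#'   `"unit_variance"`, the heatmap-tool convention).
#' @param impute_rank Rank for [svd_impute()] when `mat` has missing values.
#' @return A `pca_fit`: list with `scores` (samples x components),
#'   `loadings` (variables x components), `variance_explained`
#'   (percentages, decreasing) and `center`.
#' @export
pca_fit <- function(mat, row_scaling = c("unit_variance", "center", "none"),
                    impute_rank = NULL) {
  row_scaling <- match.arg(row_scaling)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  if (anyNA(mat)) mat <- svd_impute(mat, rank = impute_rank)
  mat <- scale_rows(mat, row_scaling)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, center = pc$center),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("pca_fit:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  ve <- x$variance_explained
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total variance\n",
              ve[1L], if (length(ve) > 1L) ve[2L] else 0))
  invisible(x)
}

#' @export
plot.pca_fit <- function(x, groups = NULL, probability = 0.95, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  ve <- x$variance_explained
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(s, col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", ve[1L]),
       ylab = sprintf("PC2 (%.1f%%)", ve[2L]), ...)
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      pts <- s[groups == g, , drop = FALSE]
      if (nrow(pts) >= 3L) {
        e <- prediction_ellipse(pts, probability)
        graphics::lines(e$boundary, col = as.integer(factor(g, levels = unique(groups))))
      }
    }
  }
  invisible(x)
}

#' Prediction ellipse for a group of 2-D scores
#'
#' Returns the ellipse such that a new observation from the same group
#' (assumed bivariate normal) falls inside with the stated probability:
#' center at the group mean, shape from the group's 2x2 covariance scaled by
#' the chi-square(2 df) quantile.
#'
#' @param scores Numeric matrix with >= 3 rows and 2 columns.
#' @param probability Coverage probability (default 0.95).
#' @return List with `center`, `cov`, `radius2` (the chi-square quantile) and
#'   `boundary` (a 100-point polygon tracing the ellipse).
#' @export
prediction_ellipse <- function(scores, probability = 0.95) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("prediction ellipse needs >= 3 group members")
  stopifnot(ncol(scores) == 2L, probability > 0, probability < 1)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  r2 <- stats::qchisq(probability, df = 2)
  theta <- seq(0, 2 * pi, length.out = 100L)
  circ <- cbind(cos(theta), sin(theta))
  boundary <- sweep(circ %*% chol(S) * sqrt(r2), 2L, ctr, `+`)
  list(center = ctr, cov = S, radius2 = r2, boundary = boundary)
}

#' Test whether points fall inside a prediction ellipse
#'
#' @param ellipse Result of [prediction_ellipse()].
#' @param points Numeric matrix with 2 columns.
#' @return Logical vector, `TRUE` where the point's squared Mahalanobis
#'   distance from the center does not exceed the ellipse radius.
#' @export
ellipse_contains <- function(ellipse, points) {
  points <- as.matrix(points)
  stats::mahalanobis(points, ellipse$center, ellipse$cov) <= ellipse$radius2
}
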