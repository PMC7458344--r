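#' Spearman rank correlation on complete pairs
#'
#' Drops pairs with a missing member, ranks with average ranks for ties, and
#' returns the rank correlation together with the number of complete pairs
#' used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `rho` (may be `NA` if a rank vector is constant, with a
#'   warning) and `n` (complete pairs).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs (", n, ")")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; Spearman correlation undefined")
    return(list(rho = NA_real_, n = n))
  }
  list(rho = stats::cor(rx, ry), n = n)
}

#' Pairwise Pearson correlation matrix
#'
#' Correlates the rows of a variables x samples matrix using pairwise
#' complete observations. Rows with zero variance (or fewer than 3 complete
#' pairs against some partner) get `NA` entries, with a warning for constant
#' variables.
#'
#' @param mat Numeric matrix, variables in rows.
#' @return Symmetric correlation matrix with unit diagonal (where defined).
#' @export
pearson_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  const <- apply(mat, 1L, function(v) stats::sd(v, na.rm = TRUE)) == 0
  if (any(const, na.rm = TRUE)) {
    warning("constant variable(s): ",
            paste(rownames(mat)[which(const)], collapse = ", "))
  }
  p <- nrow(mat)
  out <- matrix(NA_real_, p, p, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      xi <- mat[i, ]; xj <- mat[j, ]
      keep <- stats::complete.cases(xi, xj)
      r <- if (sum(keep) < 3L || stats::sd(xi[keep]) == 0 || stats::sd(xj[keep]) == 0) {
        NA_real_
      } else {
        stats::cor(xi[keep], xj[keep])
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Permutation significance of composite-IHC concordance
#'
#' Tests whether the true IHC-equivalent composite (e.g. the CD3 composite of
#' all CD3-expressing cell types) correlates with quantitative IHC better
#' than composites assembled from random cell types. Each permutation draws,
#' uniformly without replacement from the method's full cell-type catalog, a
#' random constituent set of the same cardinality as the true set, rebuilds
#' the composite, and recomputes the Spearman correlation against the IHC
#' densities. Cardinality is the only property preserved; a draw may
#' coincide with the true set by chance.
#'
#' The empirical p-value uses the add-one rule
#' `p = (1 + #\{rho_perm >= rho_obs\}) / (n_perm + 1)` (one-sided: large rho
#' means concordant), which cannot return 0 from finitely many permutations.
#' Defaults follow catalog size: 20 permutations for a 22-type catalog and
#' 100 for a 64-type catalog.
#'
#' @param decon A [deconvolution_result()].
#' @param ihc_values Named (or column-aligned) numeric vector of IHC
#'   densities per sample.
#' @param mapping A [composite_mapping()].
#' @param marker Marker to test, e.g. `"CD3"`.
#' @param n_perm Number of permutations; default 100 for catalogs larger
#'   than 32 cell types, 20 otherwise.
#' @param seed Integer seed for the permutation draws.
#' @param rule Aggregation rule passed to [build_composites()].
#' @param perm_sets Optional list of explicit constituent sets to use instead
#'   of random draws (e.g. an exhaustive enumeration); overrides `n_perm`.
#' @return A `permutation_report` with elements `marker`, `observed_rho`,
#'   `n_pairs`, `permuted_rhos`, `n_perm`, `empirical_p`, `seed`.
#' @export
permutation_significance <- function(decon, ihc_values, mapping, marker,
                                     n_perm = NULL, seed = 1L,
                                     rule = c("sum", "mean"),
                                     perm_sets = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(mapping, "composite_mapping"))
  if (!marker %in% names(mapping$markers)) {
    stop("marker ", marker, " not defined in mapping")
  }
  true_set <- mapping$markers[[marker]]
  k <- length(true_set)
  catalog <- mapping$catalog
  if (length(catalog) < k) {
    stop("catalog (", length(catalog), ") smaller than constituent count (", k, ")")
  }
  if (is.null(n_perm)) n_perm <- if (length(catalog) > 32L) 100L else 20L
  if (is.null(perm_sets) && n_perm < 1L) stop("n_perm must be >= 1")

  ihc_values <- align_ihc(ihc_values, colnames(decon))
  rho_for <- function(cons) {
    m <- composite_mapping(mapping$method, stats::setNames(list(cons), marker), catalog)
    comp <- build_composites(decon, m, rule = rule)[marker, ]
    spearman_cor(comp, ihc_values)$rho
  }
  obs <- spearman_cor(
    build_composites(decon, mapping, rule = rule)[marker, ], ihc_values)
  if (is.null(perm_sets)) {
    perm_sets <- withr_seed(seed, {
      replicate(n_perm, sample(catalog, k, replace = FALSE), simplify = FALSE)
    })
  } else {
    n_perm <- length(perm_sets)
  }
  perm_rhos <- vapply(perm_sets, rho_for, numeric(1L))
  p <- (1 + sum(perm_rhos >= obs$rho, na.rm = TRUE)) / (n_perm + 1)
  structure(list(marker = marker, observed_rho = obs$rho, n_pairs = obs$n,
                 permuted_rhos = perm_rhos, n_perm = n_perm,
                 empirical_p = p, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("Composite concordance permutation test, marker %s\n", x$marker))
  cat(sprintf("  observed Spearman rho = %.3f over %d complete pairs\n",
              x$observed_rho, x$n_pairs))
  cat(sprintf("  %d random same-size cell-type sets: empirical p = %.4g\n",
              x$n_perm, x$empirical_p))
  invisible(x)
}

#' @export
summary.permutation_report <- function(object, ...) {
  data.frame(marker = object$marker, observed_rho = object$observed_rho,
             n_pairs = object$n_pairs, n_perm = object$n_perm,
             empirical_p = object$empirical_p,
             perm_rho_max = max(object$permuted_rhos),
             stringsAsFactors = FALSE)
}

#' Plot a permutation null distribution
#'
#' Histogram of the permuted composite-IHC correlations with the observed
#' correlation marked.
#'
#' @param x A `permutation_report`.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.permutation_report <- function(x, ...) {
  graphics::hist(x$permuted_rhos, xlim = range(c(x$permuted_rhos, x$observed_rho)),
                 main = paste0(x$marker, " composite: permutation null"),
                 xlab = "Spearman rho (random cell-type sets)", ...)
  graphics::abline(v = x$observed_rho, col = "red3", lwd = 2)
  invisible(x)
}

#' Percent gene overlap between signature sets
#'
#' Entry (A, B) is `100 * |A intersect B| / |A|`, i.e. the percentage of row
#' set A's genes that also occur in column set B. The denominator is the row
#' set's own size, so the matrix is asymmetric; the diagonal is 100.
#'
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param jaccard If `TRUE`, return `100 * |A intersect B| / |A union B|`
#'   (symmetric) instead.
#' @return Numeric matrix of percentages in \[0, 100\].
#' @export
percent_match <- function(sets, jaccard = FALSE) {
  if (length(sets) < 2L) stop("need at least 2 gene sets")
  sets <- lapply(sets, unique)
  n <- length(sets)
  out <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- if (jaccard) length(union(sets[[i]], sets[[j]])) else length(sets[[i]])
      out[i, j] <- 100 * inter / denom
    }
  }
  out
}

## helpers ---------------------------------------------------------------

align_ihc <- function(ihc_values, sample_names) {
  if (!is.null(names(ihc_values)) && !is.null(sample_names)) {
    absent <- setdiff(sample_names, names(ihc_values))
    if (length(absent) == 0L) return(ihc_values[sample_names])
  }
  if (length(ihc_values) != length(sample_names)) {
    stop("IHC values cannot be aligned to deconvolution samples")
  }
  ihc_values
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
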