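#' Assign HI/LOW infiltration classes from IHC densities
#'
#' Patients with both CD3 and CD8 densities above their cutoffs are class
#' `HI`; patients below both are `LOW`; everyone else (discordant or with a
#' missing density) is `excluded`. Defaults follow the discovery design:
#' CD3 at the 75th percentile, CD8 at the median.
#'
#' @param ihc An `ihc_table` (see [read_ihc()]) or data frame with `cd3` and
#'   `cd8` columns.
#' @param cd3_rule,cd8_rule [strat_rule()]s for the two markers.
#' @return Character vector (`"HI"`, `"LOW"`, `"excluded"`) named by patient.
#' @export
assign_classes <- function(ihc,
                           cd3_rule = strat_rule("percentile", 75),
                           cd8_rule = strat_rule("median")) {
  cd3 <- stratify(ihc$cd3, cd3_rule)
  cd8 <- stratify(ihc$cd8, cd8_rule)
  lab <- rep("excluded", nrow(ihc))
  lab[!is.na(cd3) & !is.na(cd8) & cd3 == "high" & cd8 == "high"] <- "HI"
  lab[!is.na(cd3) & !is.na(cd8) & cd3 == "low" & cd8 == "low"] <- "LOW"
  stats::setNames(lab, ihc$patient)
}

#' Per-gene two-sample t-test between infiltration classes
#'
#' Class comparison of log-scale expression between `HI` and `LOW` patients:
#' a univariate two-sided two-sample t-test per gene, with a stringent
#' unadjusted alpha (default 0.001) as the false-positive control. The
#' pooled-variance (equal variance) test is the default variant; Welch is
#' available as a flag. A Benjamini-Hochberg FDR column is included for
#' reference but plays no part in selection.
#'
#' @param expr Log-scale [expression_matrix()] (transform `log2p1` or
#'   `normalized_log`), genes in rows.
#' @param labels Class labels per sample (`"HI"`/`"LOW"`/`"excluded"`), in
#'   column order or named by sample; excluded samples are dropped.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param alpha Selection threshold on the unadjusted p-value.
#' @return A `gene_signature`: data frame with one row per gene -- `gene`,
#'   `mean_hi`, `mean_low`, `mean_diff`, `t`, `df`, `p`, `fdr`, `direction`
#'   (`up_in_HI`/`up_in_LOW`), `selected`. Genes with zero variance in both
#'   classes get `NA` statistics and are never selected.
#' @export
ttest_per_gene <- function(expr, labels, variant = c("pooled", "welch"),
                           alpha = 0.001) {
  variant <- match.arg(variant)
  stopifnot(inherits(expr, "expression_matrix"))
  if (identical(attr(expr, "transform"), "tpm")) {
    stop("expression must be log-scale; apply log_transform() first")
  }
  if (!is.null(names(labels))) {
    labels <- labels[colnames(expr)]
  } else if (length(labels) != ncol(expr)) {
    stop("labels cannot be aligned to expression columns")
  }
  hi <- which(labels == "HI")
  lo <- which(labels == "LOW")
  if (length(hi) < 2L || length(lo) < 2L) {
    stop("need at least 2 patients per class (got ", length(hi), " HI, ",
         length(lo), " LOW)")
  }
  mat <- unclass(expr)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    a <- mat[i, hi]; b <- mat[i, lo]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(mean_hi = mean(a), mean_low = mean(b),
                        mean_diff = mean(a) - mean(b),
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    data.frame(mean_hi = mean(a), mean_low = mean(b),
               mean_diff = mean(a) - mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(gene = rownames(mat), stringsAsFactors = FALSE), out)
  degenerate <- is.na(out$p)
  if (any(degenerate)) {
    message("zero within-class variance in both classes; statistics withheld for: ",
            paste(out$gene[degenerate], collapse = ", "))
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$mean_diff >= 0, "up_in_HI", "up_in_LOW")
  out$selected <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  structure(out, alpha = alpha, variant = variant,
            n_hi = length(hi), n_low = length(lo),
            class = c("gene_signature", "data.frame"))
}

#' @export
print.gene_signature <- function(x, n = 10L, ...) {
  cat(sprintf("gene_signature: %d genes tested (%s t-test, %d HI vs %d LOW), %d selected at p < %g\n",
              nrow(x), attr(x, "variant"), attr(x, "n_hi"), attr(x, "n_low"),
              sum(x$selected), attr(x, "alpha")))
  ord <- order(x$p)
  print(utils::head(as.data.frame(x)[ord, c("gene", "mean_diff", "t", "p", "direction", "selected")], n),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.gene_signature <- function(object, ...) {
  list(n_genes = nrow(object), n_selected = sum(object$selected),
       n_up_in_HI = sum(object$selected & object$direction == "up_in_HI"),
       n_up_in_LOW = sum(object$selected & object$direction == "up_in_LOW"),
       alpha = attr(object, "alpha"), variant = attr(object, "variant"))
}

#' Extract the selected gene list from a signature
#'
#' @param sig A [ttest_per_gene()] result.
#' @param direction_filter Keep genes `"up_in_HI"`, `"up_in_LOW"`, or
#'   `"both"` (default).
#' @return Character vector of selected genes in ascending p-value order;
#'   empty (with a warning) if nothing passes.
#' @export
select_signature <- function(sig, direction_filter = c("both", "up_in_HI", "up_in_LOW")) {
  direction_filter <- match.arg(direction_filter)
  keep <- sig$selected
  if (direction_filter != "both") keep <- keep & sig$direction == direction_filter
  genes <- sig$gene[keep][order(sig$p[keep])]
  if (length(genes) == 0L) warning("no genes selected")
  genes
}

#' Per-gene expression z-scores against a reference distribution
#'
#' Standardizes each gene's expression against the mean and standard
#' deviation of a reference sample set, emulating expression-portal z-scores.
#' Lacking copy-number calls to pick diploid reference tumors, the default
#' reference is all samples -- an explicit approximation. The sample
#' standard deviation (n - 1 denominator) is used.
#'
#' @param expr Log-scale [expression_matrix()].
#' @param reference_samples Optional character vector of reference sample
#'   names (default: all samples). At least 3 required.
#' @return Numeric z matrix, genes x samples; genes whose reference sd is
#'   zero get `NA` rows.
#' @export
zscore_vs_reference <- function(expr, reference_samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  mat <- unclass(expr)
  if (is.null(reference_samples)) reference_samples <- colnames(mat)
  absent <- setdiff(reference_samples, colnames(mat))
  if (length(absent) > 0L) stop("unknown reference samples: ", paste(absent, collapse = ", "))
  if (length(reference_samples) < 3L) stop("reference needs >= 3 samples")
  ref <- mat[, reference_samples, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ <- apply(ref, 1L, stats::sd)
  z <- sweep(sweep(mat, 1L, mu), 1L, sd_, `/`)
  z[sd_ == 0, ] <- NA_real_
  z
}

#' Classify samples as signature-enriched
#'
#' A sample is enriched when at least one signature gene is overexpressed at
#' or beyond the threshold. The default reading is a z-score threshold of 2
#' against the reference distribution ([zscore_vs_reference()]); set
#' `scale = "log_ratio"` to instead threshold the log-expression difference
#' from the reference mean (the literal "2 log fold" reading), in which case
#' `z` should be a matrix of log-expression differences.
#'
#' @param z Genes x samples matrix of z-scores (or log-ratios).
#' @param signature_genes Character vector of signature genes; at least one
#'   must be present among the rows.
#' @param threshold Overexpression threshold (default 2).
#' @param scale Label recording which reading of the threshold `z` encodes;
#'   `"zscore"` (default) or `"log_ratio"`. Classification logic is
#'   identical; the tag documents provenance in the result.
#' @return An `enrichment_calls` data frame: per sample, `enriched` flag,
#'   number of triggering genes, and comma-separated triggering gene names;
#'   the full trigger list is in attribute `triggers`.
#' @export
classify_enriched <- function(z, signature_genes, threshold = 2,
                              scale = c("zscore", "log_ratio")) {
  scale <- match.arg(scale)
  present <- intersect(signature_genes, rownames(z))
  if (length(present) == 0L) stop("no signature gene present in z matrix rows")
  zs <- z[present, , drop = FALSE]
  triggers <- lapply(seq_len(ncol(zs)), function(j) {
    g <- present[!is.na(zs[, j]) & zs[, j] >= threshold]
    stats::setNames(zs[g, j], g)
  })
  names(triggers) <- colnames(zs)
  out <- data.frame(sample = colnames(zs),
                    enriched = lengths(triggers) > 0L,
                    n_triggers = lengths(triggers),
                    triggering_genes = vapply(triggers, function(t) {
                      paste(names(t), collapse = ",")
                    }, ""),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, triggers = triggers, threshold = threshold, scale = scale,
            class = c("enrichment_calls", "data.frame"))
}

#' Correlate signature gene expression with cell infiltrates
#'
#' Stacks the signature genes' expression rows on top of the infiltrate
#' score rows over their shared samples, computes the full Pearson
#' correlation matrix, and clusters it (Manhattan distance, average linkage
#' -- the convention used for signature-vs-infiltrate heatmaps) so that
#' co-regulated genes and cell types group together.
#'
#' @param expr Log-scale [expression_matrix()] restricted (or restrictable)
#'   to the signature genes.
#' @param infiltrates Cell type x sample score matrix (e.g. a
#'   [deconvolution_result()]).
#' @param signature_genes Optional subset of `expr` rows to use.
#' @return List with `correlation` (the joint matrix), `clustering` (the
#'   [hcluster()] result on the correlation matrix rows) and `samples`
#'   (shared sample names).
#' @export
signature_infiltrate_correlation <- function(expr, infiltrates,
                                             signature_genes = NULL) {
  emat <- unclass(expr)
  if (!is.null(signature_genes)) {
    absent <- setdiff(signature_genes, rownames(emat))
    if (length(absent) > 0L) stop("signature genes absent from expression: ",
                                  paste(absent, collapse = ", "))
    emat <- emat[signature_genes, , drop = FALSE]
  }
  imat <- unclass(infiltrates)
  shared <- intersect(colnames(emat), colnames(imat))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  joint <- rbind(emat[, shared, drop = FALSE], imat[, shared, drop = FALSE])
  cmat <- pearson_matrix(joint)
  cl <- hcluster(cmat, distance = "manhattan", linkage = "average", k = 2L)
  list(correlation = cmat, clustering = cl, samples = shared)
}
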