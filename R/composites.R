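#' Default IHC-equivalent composite mappings
#'
#' Returns the mapping from IHC markers (CD3, CD8, CD68) to the deconvolution
#' cell types that express them, for the two methods with fixed reference
#' signatures: CIBERSORT with the 22-type LM22 signature, and xCell's 64-type
#' catalog. The CD3 composite collects every CD3-expressing T-cell subset
#' (CD4 populations, CD8 populations, Tregs, gamma-delta T cells, and for
#' xCell also Th1/Th2 and NKT); CD8 collects cytotoxic subsets only; CD68
#' collects the macrophage subsets.
#'
#' Whether NKT belongs under CD3 is a judgment call (NKT cells express CD3 but
#' straddle lineages); the default includes it and can be overridden by
#' constructing a [composite_mapping()] directly.
#'
#' @param method `"cibersort_lm22"` or `"xcell64"`.
#' @return A [composite_mapping()].
#' @export
default_mapping <- function(method = c("cibersort_lm22", "xcell64")) {
  method <- tryCatch(match.arg(method), error = function(e) {
    stop("unknown method '", method[1L],
         "'; supported: cibersort_lm22, xcell64")
  })
  if (method == "cibersort_lm22") {
    catalog <- c(
      "B cells naive", "B cells memory", "Plasma cells",
      "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
      "T cells CD4 memory activated", "T cells follicular helper",
      "T cells regulatory (Tregs)", "T cells gamma delta",
      "NK cells resting", "NK cells activated", "Monocytes",
      "Macrophages M0", "Macrophages M1", "Macrophages M2",
      "Dendritic cells resting", "Dendritic cells activated",
      "Mast cells resting", "Mast cells activated",
      "Eosinophils", "Neutrophils")
    markers <- list(
      CD3 = c("T cells CD8", "T cells CD4 naive",
              "T cells CD4 memory resting", "T cells CD4 memory activated",
              "T cells follicular helper", "T cells regulatory (Tregs)",
              "T cells gamma delta"),
      CD8 = "T cells CD8",
      CD68 = c("Macrophages M0", "Macrophages M1", "Macrophages M2"))
  } else {
    catalog <- c(
      "aDC", "Adipocytes", "Astrocytes", "B-cells", "Basophils",
      "CD4+ memory T-cells", "CD4+ naive T-cells", "CD4+ T-cells",
      "CD4+ Tcm", "CD4+ Tem", "CD8+ naive T-cells", "CD8+ T-cells",
      "CD8+ Tcm", "CD8+ Tem", "cDC", "Chondrocytes",
      "Class-switched memory B-cells", "CLP", "CMP", "DC",
      "Endothelial cells", "Eosinophils", "Epithelial cells",
      "Erythrocytes", "Fibroblasts", "GMP", "Hepatocytes", "HSC", "iDC",
      "Keratinocytes", "ly Endothelial cells", "Macrophages",
      "Macrophages M1", "Macrophages M2", "Mast cells", "Megakaryocytes",
      "Melanocytes", "Memory B-cells", "MEP", "Mesangial cells",
      "Monocytes", "MPP", "MSC", "mv Endothelial cells", "Myocytes",
      "naive B-cells", "Neurons", "Neutrophils", "NK cells", "NKT",
      "Osteoblast", "pDC", "Pericytes", "Plasma cells", "Platelets",
      "Preadipocytes", "pro B-cells", "Sebocytes", "Skeletal muscle",
      "Smooth muscle", "Tgd cells", "Th1 cells", "Th2 cells", "Tregs")
    markers <- list(
      CD3 = c("CD4+ memory T-cells", "CD4+ naive T-cells", "CD4+ T-cells",
              "CD4+ Tcm", "CD4+ Tem", "CD8+ naive T-cells", "CD8+ T-cells",
              "CD8+ Tcm", "CD8+ Tem", "Tregs", "Th1 cells", "Th2 cells",
              "Tgd cells", "NKT"),
      CD8 = c("CD8+ naive T-cells", "CD8+ T-cells", "CD8+ Tcm", "CD8+ Tem"),
      CD68 = c("Macrophages", "Macrophages M1", "Macrophages M2"))
  }
  composite_mapping(method, markers, catalog)
}

#' Construct a composite mapping
#'
#' @param method Free-text method tag.
#' @param markers Named list mapping each IHC marker to the character vector
#'   of constituent cell-type names.
#' @param catalog Character vector of all cell types the method reports;
#'   every constituent must appear in it.
#' @return A `composite_mapping` object.
#' @export
composite_mapping <- function(method, markers, catalog) {
  stopifnot(is.list(markers), length(markers) > 0L, !is.null(names(markers)))
  catalog <- trimws(catalog)
  if (anyDuplicated(catalog)) stop("duplicate cell types in catalog")
  markers <- lapply(markers, trimws)
  for (m in names(markers)) {
    cons <- markers[[m]]
    if (length(cons) == 0L) stop("empty constituent list for marker ", m)
    if (anyDuplicated(cons)) stop("duplicate constituents for marker ", m)
    absent <- setdiff(cons, catalog)
    if (length(absent) > 0L) {
      stop("constituents of ", m, " not in catalog: ",
           paste(absent, collapse = ", "))
    }
  }
  structure(list(method = method, markers = markers, catalog = catalog),
            class = "composite_mapping")
}

#' @export
print.composite_mapping <- function(x, ...) {
  cat("composite_mapping (", x$method, "), catalog of ",
      length(x$catalog), " cell types\n", sep = "")
  for (m in names(x$markers)) {
    cat("  ", m, ": ", paste(x$markers[[m]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Build IHC-equivalent composite scores from deconvolution output
#'
#' For each marker in the mapping and each sample, aggregates the scores of
#' the marker's constituent cell types with the chosen rule. The default rule
#' is `sum`: combined groups of abundances (or enrichments) are additive in
#' cell counts, whereas a mean would down-weight composites with many rare
#' subtypes.
#'
#' In strict mode (default) every constituent must be present as a row of
#' `decon`; missing constituent scores propagate to `NA` composites. In
#' lenient mode absent constituents are dropped with a message, because real
#' deconvolution exports sometimes omit all-zero cell types.
#'
#' @param decon A [deconvolution_result()].
#' @param mapping A [composite_mapping()].
#' @param rule Aggregation rule, `"sum"` (default) or `"mean"`.
#' @param strict If `TRUE`, error on absent constituents.
#' @return A `composite_scores` object: marker x sample matrix with
#'   `mapping` and `rule` attributes.
#' @export
build_composites <- function(decon, mapping, rule = c("sum", "mean"),
                             strict = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(mapping, "composite_mapping"))
  rows <- trimws(rownames(decon))
  agg <- if (rule == "sum") colSums else colMeans
  out <- matrix(NA_real_, length(mapping$markers), ncol(decon),
                dimnames = list(names(mapping$markers), colnames(decon)))
  for (m in names(mapping$markers)) {
    cons <- mapping$markers[[m]]
    present <- cons %in% rows
    if (!all(present)) {
      if (strict) {
        stop("constituent(s) of ", m, " absent from deconvolution rows: ",
             paste(cons[!present], collapse = ", "))
      }
      message("marker ", m, ": dropping absent constituent(s) ",
              paste(cons[!present], collapse = ", "))
      cons <- cons[present]
      if (length(cons) == 0L) next
    }
    block <- unclass(decon)[match(cons, rows), , drop = FALSE]
    out[m, ] <- agg(block)
  }
  structure(out, mapping = mapping, rule = rule,
            class = c("composite_scores", "matrix", "array"))
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("composite_scores (%s rule, %s): %d markers x %d samples\n",
              attr(x, "rule"), attr(x, "mapping")$method, nrow(x), ncol(x)))
  print(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE])
  invisible(x)
}
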