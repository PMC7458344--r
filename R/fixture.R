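#' Packaged T-cell-infiltration discovery cohort
#'
#' Loads the packaged expression fixture: normalized log-transformed
#' expression of 38 genes associated with high T-cell infiltration, measured
#' in 28 pancreatic adenocarcinoma patients classified by quantitative IHC
#' into 15 highly infiltrated (CD3-high and CD8-high, class `HI`) and 13
#' poorly infiltrated (`LOW`) tumors. Values are stored exactly as published
#' (two decimals), so per-gene class-comparison tests on this object serve as
#' a regression anchor for the signature pipeline.
#'
#' @return A list with components `expr` (an [expression_matrix()] tagged
#'   `normalized_log`, 38 genes x 28 samples) and `classes` (named character
#'   vector of `"HI"`/`"LOW"` per sample, in column order).
#' @export
load_tcell_fixture <- function() {
  dir <- system.file("extdata", package = "immunoconcord")
  expr <- read_expression(file.path(dir, "pdac_tcell_expression.tsv"),
                          transform = "normalized_log")
  cls <- utils::read.table(file.path(dir, "pdac_tcell_classes.tsv"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  classes <- stats::setNames(cls$class, cls$sample)[colnames(expr)]
  stopifnot(!anyNA(classes))
  list(expr = expr, classes = classes)
}
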