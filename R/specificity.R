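## Tissue specificity of genes and exonic parts via the tau index.

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)` over `n >= 2` tissues:
#' 0 for uniform expression, 1 for expression confined to a single tissue.
#' Scale-invariant in the expression vector.
#'
#' @param x non-negative per-tissue expression vector.
#' @return Score in \[0, 1\], or `NA` for an all-zero vector (specificity is
#'   undefined without expression).
#' @export
tau_specificity <- function(x) {
  if (length(x) < 2L) stop("tau requires >= 2 tissues")
  if (any(!is.finite(x)) || any(x < 0))
    stop("expression values must be finite and non-negative")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Read a tissue-by-feature expression matrix
#'
#' Plain TSV: first column `tissue`, remaining column names are feature ids
#' in `chrom:start-end` form (0-based half-open).
#'
#' @param path TSV path.
#' @return numeric matrix, rows = tissues, columns = features.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1L] != "tissue")
    stop("expression matrix '", path, "': first column must be 'tissue'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$tissue
  storage.mode(m) <- "double"
  m
}

#' Tau specificity per meta-exon
#'
#' Matches matrix columns (named `chrom:start-end`) to meta-exon
#' coordinates and scores each mapped meta-exon; unmapped columns are
#' skipped with a warning.
#'
#' @param expression tissue x feature matrix, see [read_expression_matrix()].
#' @param meta_exons data.frame from [build_meta_exons()].
#' @return data.frame with columns `feature`, `chrom`, `start`, `end`,
#'   `tau`.
#' @export
exon_specificity_table <- function(expression, meta_exons) {
  feat <- sprintf("%s:%d-%d", meta_exons$chrom, meta_exons$start,
                  meta_exons$end)
  unmapped <- setdiff(colnames(expression), feat)
  if (length(unmapped))
    warning("skipping expression column(s) matching no meta-exon: ",
            paste(unmapped, collapse = ", "))
  keep <- intersect(feat, colnames(expression))
  i <- match(keep, feat)
  data.frame(feature = keep, chrom = meta_exons$chrom[i],
             start = meta_exons$start[i], end = meta_exons$end[i],
             tau = vapply(keep, function(f)
               tau_specificity(expression[, f]), numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
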