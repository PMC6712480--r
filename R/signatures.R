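#' Geometric-mean signature over a gene list
#'
#' Summarizes each sample by the geometric mean of the listed genes'
#' expression, computed in log space for numerical stability:
#' `exp(mean(log(x + eps)))`. With the default `"auto"` pseudocount policy
#' `eps` is 0 when every value in `expr` is strictly positive and half the
#' smallest positive value in the matrix otherwise, so zero-containing
#' RNA-seq style matrices still yield strictly positive signatures.
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of gene symbols, all present in `expr`.
#' @param pseudocount `"auto"` (default), `"none"`, or a nonnegative number.
#' @param log_transform If `TRUE`, apply `log2(x + 1)` to the expression
#'   values before averaging (geometric mean of the log2 scale).
#' @return Named numeric vector, one strictly positive value per sample.
#' @examples
#' m <- expression_matrix(matrix(c(4, 9), 2, 1,
#'   dimnames = list(c("A", "B"), "S1")))
#' geometric_signature(m, c("A", "B"))  # sqrt(4 * 9) = 6
#' @export
geometric_signature <- function(expr, genes, pseudocount = "auto",
                                log_transform = FALSE) {
  genes <- toupper(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ", paste(missing, collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  eps <- if (identical(pseudocount, "auto")) {
    if (all(x > 0)) 0 else {
      pos <- expr[expr > 0]
      if (!length(pos)) stop("expression matrix is all zero")
      min(pos) / 2
    }
  } else if (identical(pseudocount, "none")) 0 else {
    stopifnot(is.numeric(pseudocount), pseudocount >= 0)
    pseudocount
  }
  if (eps == 0 && any(x == 0)) {
    zg <- genes[apply(x == 0, 1, any)]
    stop("zero expression in gene(s) ", paste(zg, collapse = ", "),
         " with zero pseudocount; use pseudocount = 'auto' or a positive value")
  }
  exp(colMeans(log(x + eps)))
}

#' Compute writer/reader/eraser (W/R/E) signatures
#'
#' W is the geometric mean of METTL3 and METTL14, R of YTHDF1/YTHDF2/YTHDF3,
#' and E of ALKBH5 and FTO, per sample. The three signatures summarize the
#' expression of the m6A writing, reading and erasing machinery; high W/R
#' and low E indicate augmented m6A modification.
#'
#' @inheritParams geometric_signature
#' @return A `data.frame` of class `"signature_table"` with columns
#'   `sample`, `W`, `R`, `E` (samples in expression-matrix order).
#' @export
compute_wre <- function(expr, pseudocount = "auto", log_transform = FALSE) {
  reg <- m6a_regulators()
  sig <- function(g) geometric_signature(expr, g, pseudocount, log_transform)
  out <- data.frame(
    sample = colnames(expr),
    W = unname(sig(reg$writers)),
    R = unname(sig(reg$readers)),
    E = unname(sig(reg$erasers)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Write a signature table to TSV
#' @param sig A `signature_table` from [compute_wre()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise correlation with significance
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) between two paired vectors, with a two-sided P value from the
#' t approximation. Pairs with a missing value in either vector are removed
#' first. A zero-variance vector yields a flagged, `NA`-coefficient result
#' rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param label Optional pair label carried into the result.
#' @return A one-row `data.frame`: `pair`, `method`, `coefficient`, `p_value`,
#'   `n`, `degenerate` (logical flag for zero-variance input).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"), label = "x~y") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >=3 paired finite observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(pair = label, method = method, coefficient = NA_real_,
                      p_value = NA_real_, n = n, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  ct <- if (method == "pearson") stats::cor.test(x, y, method = "pearson")
        else suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(pair = label, method = method,
             coefficient = unname(ct$estimate), p_value = ct$p.value,
             n = n, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' All pairwise correlations among W, R and E signatures
#'
#' @param sig A `signature_table` from [compute_wre()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame with one row per unordered signature pair
#'   (W~R, W~E, R~E). No multiplicity correction is applied.
#' @export
signature_correlations <- function(sig, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- list(c("W", "R"), c("W", "E"), c("R", "E"))
  do.call(rbind, lapply(pairs, function(p)
    correlate(sig[[p[1]]], sig[[p[2]]], method, label = paste0(p[1], "~", p[2]))))
}
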