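# VanRaden genomic relationship matrix (method 1, the linear kernel).

#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)) where W is the column-centered
#' marker matrix (each column minus twice its allele frequency p_k =
#' column mean / 2). Allele frequencies are always estimated from the
#' matrix passed in, so an augmented (real-valued) matrix is centered with
#' its own frequencies.
#'
#' @param m complete (no missing) marker matrix, lines x markers; raw
#'   dosages or real-valued augmented rows.
#' @return Symmetric positive semidefinite matrix with line ids as
#'   dimnames.
#' @export
vanraden_grm <- function(m) {
  .check_markers(m, raw = FALSE)
  if (anyNA(m)) stop("marker matrix contains missing values; impute first")
  p <- colMeans(m) / 2
  cv <- apply(m, 2, stats::var)
  if (all(cv < .Machine$double.eps))
    stop("degenerate marker matrix: every marker has zero variance")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps)
    stop("degenerate marker matrix: 2*sum(p*(1-p)) is zero")
  w <- sweep(m, 2, 2 * p)
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2
  dimnames(g) <- list(rownames(m), rownames(m))
  g
}

#' Extract a block of a GRM by line ids
#'
#' @param g GRM with line ids as dimnames.
#' @param rows,cols character vectors of line ids.
#' @return The `length(rows)` x `length(cols)` block in requested order.
#' @export
grm_submatrix <- function(g, rows, cols = rows) {
  unknown <- setdiff(c(rows, cols), rownames(g))
  if (length(unknown) > 0)
    stop("unknown line id(s): ", paste(unknown, collapse = ", "))
  g[rows, cols, drop = FALSE]
}

#' Write a GRM as delimited text
#'
#' @param g GRM.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_grm <- function(g, path, dialect = c("csv", "tsv")) {
  sep <- .sep_for(match.arg(dialect))
  df <- data.frame(line_id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
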