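#' Pearson correlation screen with significance flags
#'
#' Product-moment correlations between all pairs of variables with two-sided
#' t-test significance at the given level.
#'
#' @param x Numeric matrix or data.frame, cases in rows, variables in
#'   columns; at least 3 complete cases are required.
#' @param alpha Significance level for the flags.
#' @return Object of class `"correlation_report"`: correlation matrix `r`,
#'   p-value matrix `p`, logical matrix `significant`, sample size `n`,
#'   `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' pearson_matrix(x)
pearson_matrix <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete cases", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(x)
  # two-sided t test on n-2 df; diagonal fixed afterwards
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, significant = p < alpha, n = n,
                 alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (n = %d, * p < %s)\n", x$n,
              format(x$alpha)))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        ifelse(x$significant & row(x$r) != col(x$r), "*", " ")),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Principal component analysis on standardised variables
#'
#' Centres and scales each variable to unit variance, then eigendecomposes
#' the correlation matrix (via [stats::prcomp()]). Loading columns are sign
#' anchored so that each component's largest-magnitude loading is positive;
#' explained-variance percentages sum to 100.
#'
#' @param x Numeric matrix or data.frame, at least 3 cases and 2 variables.
#' @return Object of class `"ms_pca"`: `loadings` (variables x components),
#'   `scores` (cases x components), `explained_variance_pct`, `sdev`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), ncol = 4)
#' ms_pca(x)
ms_pca <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 cases", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_pct = expl, sdev = pc$sdev,
                 center = pc$center, scale = pc$scale),
            class = "ms_pca")
}

#' @export
print.ms_pca <- function(x, digits = 3, ...) {
  cat("Principal components of standardised variables\n")
  cat("  explained variance (%):",
      paste(round(x$explained_variance_pct, 1), collapse = ", "), "\n")
  cat("  loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Clustered heat map of an impact matrix
#'
#' Hierarchically clusters the rows and columns of a finite matrix
#' (Euclidean distance, complete linkage by default), optionally renders a
#' heat map, and returns the dendrogram leaf orders. Rows or columns that
#' are entirely `NA` (the undefined reference line of an impact matrix) are
#' dropped before clustering. A single remaining row or column is left
#' unclustered in input order.
#'
#' @param m Numeric matrix with dimnames.
#' @param file Optional path; when given, the heat map is written there
#'   (device chosen from the extension: `.png` or `.pdf`).
#' @param plot Draw the heat map on the active device.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Invisibly, a list with `row_order`, `col_order` (leaf labels),
#'   `row_hclust`, `col_hclust` (or `NULL` when clustering was skipped) and
#'   the clustered `matrix`.
#' @export
cluster_heatmap <- function(m, file = NULL, plot = FALSE,
                            distance = "euclidean", linkage = "complete") {
  stopifnot(is.matrix(m))
  m <- m[rowSums(!is.na(m)) > 0, colSums(!is.na(m)) > 0, drop = FALSE]
  if (any(!is.finite(m)))
    stop("matrix has non-finite entries after dropping undefined lines",
         call. = FALSE)
  hc_row <- if (nrow(m) > 1)
    stats::hclust(stats::dist(m, method = distance), method = linkage)
  hc_col <- if (ncol(m) > 1)
    stats::hclust(stats::dist(t(m), method = distance), method = linkage)
  row_order <- if (is.null(hc_row)) rownames(m) else rownames(m)[hc_row$order]
  col_order <- if (is.null(hc_col)) colnames(m) else colnames(m)[hc_col$order]

  if (!is.null(file) || plot) {
    draw <- function() {
      pheatmap::pheatmap(
        m,
        cluster_rows = if (is.null(hc_row)) FALSE else hc_row,
        cluster_cols = if (is.null(hc_col)) FALSE else hc_col,
        silent = FALSE)
    }
    if (!is.null(file)) {
      ext <- tolower(tools::file_ext(file))
      if (ext == "pdf") grDevices::pdf(file, width = 7, height = 6)
      else grDevices::png(file, width = 900, height = 800, res = 120)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw()
    } else draw()
  }
  invisible(list(row_order = row_order, col_order = col_order,
                 row_hclust = hc_row, col_hclust = hc_col, matrix = m))
}
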