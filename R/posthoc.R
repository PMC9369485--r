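#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons of group means in a balanced design using the
#' studentized-range distribution: for groups `i`, `j` the statistic is
#' `q = |mean_i - mean_j| / sqrt(mse / n)` referred to the range distribution
#' with `k` groups and the error degrees of freedom, which controls the
#' family-wise error rate across all pairs.
#'
#' @param means Named numeric vector of group means.
#' @param mse Error mean square of the underlying ANOVA (> 0).
#' @param df_error Error degrees of freedom (>= 1).
#' @param n_per_cell Replicates behind each mean (>= 2, equal across groups).
#' @param alpha Family-wise significance level.
#' @return Object of class `"tukey_hsd"`: symmetric p-value matrix `p` with
#'   unit diagonal, statistic matrix `q`, and the inputs.
#' @export
#' @examples
#' tk <- tukey_hsd(c(a = 1, b = 1.2, c = 5), mse = 0.2, df_error = 12,
#'                 n_per_cell = 5)
#' tk$p
tukey_hsd <- function(means, mse, df_error, n_per_cell, alpha = 0.05) {
  if (is.null(names(means))) names(means) <- seq_along(means)
  k <- length(means)
  if (k < 2) stop("need at least two means", call. = FALSE)
  if (!is.finite(mse) || mse <= 0)
    stop("parameter error: 'mse' must be positive", call. = FALSE)
  if (df_error < 1) stop("parameter error: 'df_error' must be >= 1", call. = FALSE)
  if (n_per_cell < 2) stop("parameter error: 'n_per_cell' must be >= 2", call. = FALSE)
  se <- sqrt(mse / n_per_cell)
  q <- abs(outer(means, means, "-")) / se
  # p is symmetric: evaluate the range CDF on the upper triangle only
  p <- matrix(1, k, k, dimnames = dimnames(q))
  up <- upper.tri(q)
  p[up] <- stats::ptukey(q[up], nmeans = k, df = df_error,
                         lower.tail = FALSE)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(p = p, q = q, means = means, mse = mse,
                 df_error = df_error, n_per_cell = n_per_cell, alpha = alpha),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, digits = 4, ...) {
  cat(sprintf("Tukey HSD, %d groups, error df = %s\n",
              length(x$means), format(x$df_error)))
  print(round(x$p, digits))
  invisible(x)
}

#' Compact letter display of homogeneous groups
#'
#' Assigns letters to group means so that two groups share at least one
#' letter exactly when their pairwise comparison is non-significant at
#' `alpha` (the insert-and-absorb construction). Letter `a` is anchored to
#' the largest mean, matching the convention of marking top treatments first.
#'
#' @param means Named numeric vector of group means.
#' @param p Symmetric pairwise p-value matrix over the same groups (e.g. from
#'   [tukey_hsd()]), or a `"tukey_hsd"` object.
#' @param alpha Significance level.
#' @return Object of class `"letter_display"`: a data.frame with columns
#'   `level`, `mean`, `letters`, ordered by decreasing mean.
#' @export
#' @examples
#' tk <- tukey_hsd(c(a = 1, b = 1.2, c = 5), mse = 0.2, df_error = 12,
#'                 n_per_cell = 5)
#' letter_display(tk$means, tk$p)
letter_display <- function(means, p, alpha = 0.05) {
  if (inherits(p, "tukey_hsd")) {
    if (missing(means)) means <- p$means
    p <- p$p
  }
  if (is.null(names(means))) names(means) <- seq_along(means)
  k <- length(means)
  stopifnot(is.matrix(p), nrow(p) == k, ncol(p) == k)
  if (!is.null(rownames(p))) p <- p[names(means), names(means), drop = FALSE]

  ord <- order(-means)  # stable: ties keep input order
  sig <- p[ord, ord, drop = FALSE] < alpha

  # insert-and-absorb over membership columns; start with all in one column
  cols <- list(rep(TRUE, k))
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && !drop[j] && all(cols[[i]] <= cols[[j]]) &&
          (any(cols[[i]] != cols[[j]]) || i > j))
        drop[i] <- TRUE
    }
    cols[!drop]
  }
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[i, j]) next
    hit <- vapply(cols, function(co) co[i] && co[j], logical(1))
    if (!any(hit)) next
    for (idx in which(hit)) {
      a <- cols[[idx]]; b <- a
      a[i] <- FALSE; b[j] <- FALSE
      cols[[idx]] <- a
      cols[[length(cols) + 1]] <- b
    }
    cols <- absorb(cols)
  }
  # order columns by their top (largest-mean) member so 'a' marks the top
  first <- vapply(cols, function(co) which(co)[1], integer(1))
  cols <- cols[order(first)]
  lab <- make_letter_labels(length(cols))
  letters_per <- vapply(seq_len(k), function(i)
    paste(lab[vapply(cols, `[[`, logical(1), i)], collapse = ""), character(1))

  out <- data.frame(level = names(means)[ord], mean = unname(means[ord]),
                    letters = letters_per, stringsAsFactors = FALSE)
  structure(out, alpha = alpha, class = c("letter_display", "data.frame"))
}

make_letter_labels <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(n)]
}

#' @export
print.letter_display <- function(x, digits = 4, ...) {
  cat(sprintf("Homogeneous groups (alpha = %s)\n", format(attr(x, "alpha"))))
  y <- as.data.frame(x)
  y$mean <- signif(y$mean, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
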