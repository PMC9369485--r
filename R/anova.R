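#' Fit the balanced two-way factorial model to one response
#'
#' The central model of the package: for a response measured in a balanced
#' contaminant-by-sorbent factorial with replicated cells, fits the two-way
#' ANOVA `value ~ contaminant * sorbent`, partitions the total sum of squares
#' into contaminant, sorbent, interaction and error (type I, identical to
#' type III under balance), expresses each term's share of the total SS as an
#' eta-squared percentage, and attaches Tukey HSD comparisons with compact
#' letter displays at three levels: the full cell grid, sorbent means
#' averaged over contaminants, and contaminant means averaged over sorbents
#' (the two marginal comparisons are one-way ANOVAs on the pooled data).
#'
#' @param x A `"measurement_table"`, or a data.frame with columns
#'   `contaminant`, `sorbent`, `replicate`, `response`, `value` plus a
#'   `design` argument.
#' @param response Name of the response to fit.
#' @param alpha Significance level for the letter displays.
#' @param design Required when `x` is a plain data.frame.
#' @return An object of class `"ms_anova"` with components `anova_table`
#'   (term, SS, df, MS, F, p), `eta2` (percent of total SS per term,
#'   including error), `cell_means`, `mse`, `df_error`, `n_per_cell`,
#'   `tukey` and `letters` (lists with elements `cells`, `sorbent`,
#'   `contaminant`), `alpha`, `response`, `data`.
#' @seealso [summary.ms_anova()], [simulate.ms_anova()], [tukey_hsd()],
#'   [letter_display()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' tab <- generate_measurements(cfg)
#' fit <- ms_anova(tab, "Org")
#' fit
#' coef(fit)
ms_anova <- function(x, response, alpha = 0.05, design = NULL) {
  if (!inherits(x, "measurement_table")) {
    if (is.null(design))
      stop("'design' is required when 'x' is not a measurement_table",
           call. = FALSE)
    x <- measurement_table(x, design)
  }
  design <- attr(x, "design")
  sub <- x[x$response == response, , drop = FALSE]
  if (!nrow(sub))
    stop("response '", response, "' not present in table", call. = FALSE)
  sub <- droplevels(as.data.frame(sub))

  n_cell <- table(sub$contaminant, sub$sorbent)
  if (length(unique(as.vector(n_cell))) != 1L)
    stop("balance error: unequal replicate counts across cells", call. = FALSE)
  n_per_cell <- as.vector(n_cell)[1]
  if (n_per_cell < 2L)
    stop("balance error: need >= 2 replicates per cell for an error term",
         call. = FALSE)

  fit <- stats::aov(value ~ contaminant * sorbent, data = sub)
  aovtab <- stats::anova(fit)
  term_map <- c("contaminant" = "contaminant", "sorbent" = "sorbent",
                "contaminant:sorbent" = "interaction",
                "Residuals" = "error")
  tab <- data.frame(
    term = unname(term_map[rownames(aovtab)]),
    SS = aovtab$`Sum Sq`, df = aovtab$Df, MS = aovtab$`Mean Sq`,
    F = aovtab$`F value`, p = aovtab$`Pr(>F)`,
    stringsAsFactors = FALSE)
  ss_total <- sum(tab$SS)
  eta2 <- stats::setNames(100 * tab$SS / ss_total, tab$term)
  mse <- tab$MS[tab$term == "error"]
  df_error <- tab$df[tab$term == "error"]

  mu <- tapply(sub$value, list(sub$sorbent, sub$contaminant), mean)
  cellnames <- outer(rownames(mu), colnames(mu),
                     function(s, c) paste(c, s, sep = ":"))
  cell_vec <- stats::setNames(as.vector(mu), as.vector(cellnames))
  tk_cells <- tukey_hsd(cell_vec, mse, df_error, n_per_cell, alpha)

  one_way <- function(fac) {
    f1 <- stats::aov(value ~ g, data = data.frame(value = sub$value,
                                                  g = sub[[fac]]))
    a1 <- stats::anova(f1)
    gm <- tapply(sub$value, sub[[fac]], mean)
    tukey_hsd(gm, a1$`Mean Sq`[2], a1$Df[2],
              n_per_cell = nrow(sub) / nlevels(sub[[fac]]), alpha = alpha)
  }
  tk_sorb <- one_way("sorbent")
  tk_cont <- one_way("contaminant")

  lets <- lapply(list(cells = tk_cells, sorbent = tk_sorb,
                      contaminant = tk_cont),
                 function(tk) letter_display(tk$means, tk$p, alpha))

  structure(
    list(response = response, data = sub, design = design,
         anova_table = tab, eta2 = eta2, cell_means = mu,
         mse = mse, df_error = df_error, n_per_cell = n_per_cell,
         tukey = list(cells = tk_cells, sorbent = tk_sorb,
                      contaminant = tk_cont),
         letters = lets, alpha = alpha, call = match.call()),
    class = "ms_anova")
}

#' Eta-squared effect contributions
#'
#' Each ANOVA term's share of the total sum of squares, in percent. The
#' shares of contaminant, sorbent, interaction and error sum to 100.
#'
#' @param object An `"ms_anova"` fit.
#' @return Named numeric vector of percentages.
#' @export
eta_squared <- function(object) {
  stopifnot(inherits(object, "ms_anova"))
  object$eta2
}

#' @export
print.ms_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way factorial ANOVA: %s (%d cells x %d replicates)\n\n",
              x$response, length(x$cell_means), x$n_per_cell))
  tab <- x$anova_table
  tab$eta2_pct <- x$eta2[tab$term]
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarise a factorial fit
#'
#' @param object An `"ms_anova"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.ms_anova"`; printing shows the ANOVA
#'   table with eta-squared shares, the cell means with their homogeneous
#'   group letters, and the two marginal letter displays.
#' @export
summary.ms_anova <- function(object, ...) {
  structure(list(fit = object), class = "summary.ms_anova")
}

#' @export
print.summary.ms_anova <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nCell means with homogeneous groups (alpha =", f$alpha, "):\n")
  print(f$letters$cells, digits = digits)
  cat("\nSorbent means (averaged over contaminants):\n")
  print(f$letters$sorbent, digits = digits)
  cat("\nContaminant means (averaged over sorbents):\n")
  print(f$letters$contaminant, digits = digits)
  invisible(x)
}

#' @export
coef.ms_anova <- function(object, ...) object$cell_means

#' @export
fitted.ms_anova <- function(object, ...) {
  with(object$data,
       object$cell_means[cbind(as.character(sorbent),
                               as.character(contaminant))])
}

#' @export
residuals.ms_anova <- function(object, ...) {
  object$data$value - fitted(object)
}

#' Predicted cell means for new treatment combinations
#'
#' @param object An `"ms_anova"` fit.
#' @param newdata Data.frame with columns `contaminant` and `sorbent`;
#'   defaults to the full factorial grid.
#' @param ... Unused.
#' @return Numeric vector of cell means.
#' @export
predict.ms_anova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- expand.grid(sorbent = rownames(object$cell_means),
                           contaminant = colnames(object$cell_means),
                           stringsAsFactors = FALSE)
  s <- as.character(newdata$sorbent)
  co <- as.character(newdata$contaminant)
  bad <- !(s %in% rownames(object$cell_means)) |
    !(co %in% colnames(object$cell_means))
  if (any(bad))
    stop("level error: unknown treatment combination(s) in 'newdata'",
         call. = FALSE)
  object$cell_means[cbind(s, co)]
}

#' Parametric simulation from a factorial fit
#'
#' Draws new replicate tables from the fitted cell means with homoscedastic
#' Gaussian errors at the estimated error standard deviation (the model the
#' ANOVA assumes).
#'
#' @param object An `"ms_anova"` fit.
#' @param nsim Number of simulated tables.
#' @param seed Optional seed for reproducibility.
#' @param ... Unused.
#' @return A list of `"measurement_table"` objects of the same shape as the
#'   fitted data.
#' @export
simulate.ms_anova <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$mse)
  mu <- fitted(object)
  template <- object$data
  lapply(seq_len(nsim), function(i) {
    template$value <- stats::rnorm(length(mu), mean = mu, sd = sigma)
    measurement_table(template, object$design)
  })
}

#' Interaction plot of cell means
#'
#' @param x An `"ms_anova"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ms_anova <- function(x, ...) {
  mu <- x$cell_means
  graphics::matplot(seq_len(ncol(mu)), t(mu), type = "b", pch = 19,
                    lty = 1, xaxt = "n", xlab = "contaminant",
                    ylab = x$response, main = "Cell means", ...)
  graphics::axis(1, at = seq_len(ncol(mu)), labels = colnames(mu))
  graphics::legend("topright", legend = rownames(mu), col = seq_len(nrow(mu)),
                   lty = 1, pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}
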