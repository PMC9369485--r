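#' Daily colony-emergence series for one plate
#'
#' Counts of colonies first visible on each day of the observation window.
#' The colony development and ecophysiological diversity indices are defined
#' only for plates on which at least one colony appeared.
#'
#' @param counts Non-negative integer vector, `counts[d]` = colonies first
#'   visible on day `d`.
#' @param contaminant,sorbent,group,replicate Optional labels (microbial
#'   group is conventionally one of `"Org"`, `"Act"`, `"Fun"`).
#' @return An object of class `"emergence_series"`.
#' @export
#' @examples
#' s <- emergence_series(c(5, 5, rep(0, 8)))
#' colony_development(s)
emergence_series <- function(counts, contaminant = NA_character_,
                             sorbent = NA_character_, group = NA_character_,
                             replicate = NA_integer_) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  structure(list(counts = as.integer(round(counts)),
                 contaminant = contaminant, sorbent = sorbent,
                 group = group, replicate = replicate),
            class = "emergence_series")
}

#' @export
print.emergence_series <- function(x, ...) {
  cat(sprintf("Emergence series (%d days, %d colonies)\n",
              length(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Day-of-first-appearance profile of a plate
#'
#' Normalises an emergence series to the fraction of all colonies first
#' appearing on each day. An empty plate (zero colonies in total) has no
#' profile and raises an error.
#'
#' @param s An [emergence_series()] or a raw count vector.
#' @return Numeric vector of class `"day_profile"` summing to 1.
#' @export
day_profile <- function(s) {
  if (inherits(s, "day_profile")) return(s)
  counts <- if (inherits(s, "emergence_series")) s$counts else {
    s <- emergence_series(s); s$counts
  }
  total <- sum(counts)
  if (total <= 0)
    stop("undefined index: no colonies appeared during the observation window",
         call. = FALSE)
  structure(counts / total, class = "day_profile")
}

#' Colony development index (CD)
#'
#' A weighted sum over observation days of the fraction of colonies first
#' appearing on each day, each fraction divided by its day number, times 100:
#' `CD = 100 * sum(p_d / d)`. CD is 100 when all colonies appear on day 1
#' (a fast-growing, r-strategist community) and `100/D` when all appear on
#' the last of `D` days.
#'
#' @param p A `"day_profile"`, an [emergence_series()], or raw counts.
#' @return CD value in `[100/D, 100]`.
#' @export
#' @examples
#' colony_development(c(10, 0, 0, 0, 0, 0, 0, 0, 0, 0))  # 100
colony_development <- function(p) {
  p <- day_profile(p)
  100 * sum(p / seq_along(p))
}

#' Ecophysiological diversity index (EP)
#'
#' Shannon-type entropy (base-10 logarithm) of the day-of-first-appearance
#' distribution: `EP = -sum(p_d * log10(p_d))`, with the entropy convention
#' that zero fractions contribute zero. EP is 0 when all colonies appear on
#' one day and `log10(D)` when appearance is uniform over `D` days.
#'
#' @inheritParams colony_development
#' @return EP value in `[0, log10(D)]`.
#' @export
#' @examples
#' ecophysiological_diversity(rep(10, 10))  # 1
ecophysiological_diversity <- function(p) {
  p <- day_profile(p)
  pos <- p[p > 0]
  -sum(pos * log10(pos))
}

#' Relative impact factor of a treatment
#'
#' The shared kernel of the metal and sorbent impact indices: the relative
#' change of a response under treatment compared to its reference,
#' `a_treated / a_reference - 1`. Negative values are suppression, positive
#' values stimulation; multiply by 100 for percent.
#'
#' @param a_treated Response level under treatment (>= 0); vectorised.
#' @param a_reference Response level in the reference condition (> 0);
#'   vectorised.
#' @return `a_treated / a_reference - 1`.
#' @export
#' @examples
#' impact_factor(26.42, 30.62)  # Cu suppression of organotrophic bacteria
impact_factor <- function(a_treated, a_reference) {
  if (any(!is.finite(a_reference)) || any(a_reference <= 0))
    stop("undefined reference: 'a_reference' must be positive", call. = FALSE)
  if (any(!is.finite(a_treated)) || any(a_treated < 0))
    stop("'a_treated' must be non-negative", call. = FALSE)
  a_treated / a_reference - 1
}

new_index_matrix <- function(m, index, response) {
  structure(m, index = index, response = response,
            class = c("index_matrix", class(m)))
}

#' Metal and sorbent impact-factor matrices for one response
#'
#' Computes per-cell treatment means and derives two impact matrices:
#' `IF_HM(metal, sorbent)` compares each contaminated cell to the
#' uncontaminated cell under the same sorbent, and `IF_Ad(metal, sorbent)`
#' compares each amended cell to the sorbent-free cell under the same
#' contaminant. Cells whose treatment equals its own reference (the
#' uncontaminated column of `IF_HM`, the sorbent-free row of `IF_Ad`) are
#' undefined and carried as `NA`.
#'
#' @param x A `"measurement_table"`.
#' @param response Response to analyse.
#' @param percent Return values multiplied by 100.
#' @return List with components `IF_HM` and `IF_Ad`, each an
#'   `"index_matrix"` (sorbents x contaminants).
#' @export
#' @examples
#' tab <- greenhouse_measurements("microbial")
#' index_matrices(tab, "Org")$IF_Ad["Molecular sieve", "Ni"]
index_matrices <- function(x, response, percent = FALSE) {
  mu <- cell_means(x, response)
  design <- attr(x, "design")
  ref_c <- design$contaminants[1]
  ref_s <- design$sorbents[1]
  if (!ref_c %in% colnames(mu) || !ref_s %in% rownames(mu))
    stop("reference levels '", ref_c, "'/'", ref_s,
         "' absent from the table", call. = FALSE)
  check_ref <- function(v, what) {
    bad <- names(v)[!is.finite(v) | v <= 0]
    if (length(bad))
      stop("undefined reference: non-positive ", what, " mean in cell(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_ref(mu[, ref_c], paste0("(", ref_c, ", sorbent)"))
  check_ref(mu[ref_s, ], paste0("(", ref_s, ", contaminant)"))

  if_hm <- sweep(mu, 1, mu[, ref_c], "/") - 1
  if_hm[, ref_c] <- NA_real_
  if_ad <- sweep(mu, 2, mu[ref_s, ], "/") - 1
  if_ad[ref_s, ] <- NA_real_
  if (percent) {
    if_hm <- if_hm * 100
    if_ad <- if_ad * 100
  }
  list(IF_HM = new_index_matrix(if_hm, "IF_HM", response),
       IF_Ad = new_index_matrix(if_ad, "IF_Ad", response))
}

#' CD and EP for a collection of plates
#'
#' Computes both colony indices per emergence series; empty plates are
#' reported as `NA` with a warning rather than an error so that a batch of
#' plates can be summarised in one pass.
#'
#' @param series A list of [emergence_series()] objects.
#' @return Data.frame with one row per plate: labels, total colony count,
#'   `CD` and `EP`.
#' @export
colony_indices <- function(series) {
  stopifnot(is.list(series))
  rows <- lapply(series, function(s) {
    stopifnot(inherits(s, "emergence_series"))
    total <- sum(s$counts)
    if (total > 0) {
      p <- day_profile(s)
      cd <- colony_development(p); ep <- ecophysiological_diversity(p)
    } else {
      cd <- NA_real_; ep <- NA_real_
    }
    data.frame(contaminant = s$contaminant, sorbent = s$sorbent,
               group = s$group, replicate = s$replicate,
               total = total, CD = cd, EP = ep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$CD))
    warning(sum(is.na(out$CD)), " empty plate(s): CD/EP undefined",
            call. = FALSE)
  out
}

#' Write an index matrix as rectangular CSV
#'
#' Rows are sorbents, columns contaminants; undefined cells are written
#' blank. Values are serialised with enough digits to round-trip through
#' [read_index_matrix()] to at least 12 significant digits.
#'
#' @param m An `"index_matrix"` (or plain numeric matrix with dimnames).
#' @param path Output file path.
#' @export
write_index_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  vals <- matrix(ifelse(is.na(m), NA_character_,
                        format(m, digits = 17, trim = TRUE,
                               scientific = FALSE)),
                 nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(sorbent = rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read an index matrix written by [write_index_matrix()]
#'
#' @param path CSV file path.
#' @param index,response Optional metadata to attach.
#' @return An `"index_matrix"`; blank cells become `NA`.
#' @export
read_index_matrix <- function(path, index = NA_character_,
                              response = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  new_index_matrix(m, index, response)
}

#' @export
print.index_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Index matrix %s (%s)\n",
              attr(x, "index") %||% "", attr(x, "response") %||% ""))
  print(round(unclass(x), digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
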