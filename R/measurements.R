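#' Construct and validate a tidy measurement table
#'
#' The replicate-level representation every analysis consumes: one row per
#' (contaminant, sorbent, replicate, response) with a numeric value. Level
#' labels are matched against the design as case-sensitive exact strings, and
#' every (contaminant, sorbent, response) cell must carry exactly the
#' replicate count the design declares for that response's family.
#'
#' @param df A data.frame with columns `contaminant`, `sorbent`, `replicate`,
#'   `response`, `value`.
#' @param design An [experiment_design()].
#' @return A data.frame of class `"measurement_table"` carrying the design as
#'   an attribute, with contaminant and sorbent as factors in design order.
#' @export
measurement_table <- function(df, design) {
  stopifnot(inherits(design, "experiment_design"))
  required <- c("contaminant", "sorbent", "replicate", "response", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[required]
  df$contaminant <- as.character(df$contaminant)
  df$sorbent <- as.character(df$sorbent)
  df$response <- as.character(df$response)
  df$value <- as.numeric(df$value)

  bad_c <- setdiff(unique(df$contaminant), design$contaminants)
  bad_s <- setdiff(unique(df$sorbent), design$sorbents)
  if (length(bad_c) || length(bad_s))
    stop("level error: unknown label(s): ",
         paste(c(bad_c, bad_s), collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$value)))
    stop("values must be finite", call. = FALSE)

  nonneg_fams <- c("microbial", "yield")
  for (resp in unique(df$response)) {
    fam <- design$families[resp]
    if (!is.na(fam) && fam %in% nonneg_fams &&
        any(df$value[df$response == resp] < 0))
      stop("negative values in non-negative response '", resp, "'", call. = FALSE)
  }

  # every declared cell complete, at exactly the declared replicate count
  counts <- as.data.frame(table(contaminant = df$contaminant,
                                sorbent = df$sorbent,
                                response = df$response))
  offending <- character(0)
  for (resp in unique(df$response)) {
    expected <- design_replicates(design, resp)
    sub <- counts[counts$response == resp, ]
    bad <- sub[sub$Freq != expected, ]
    if (nrow(bad))
      offending <- c(offending, sprintf("(%s, %s, %s): %d != %d",
                                        bad$contaminant, bad$sorbent,
                                        resp, bad$Freq, expected))
  }
  if (length(offending))
    stop("design-mismatch error: wrong replicate count in cell(s):\n  ",
         paste(offending, collapse = "\n  "), call. = FALSE)

  df$contaminant <- factor(df$contaminant, levels = design$contaminants)
  df$sorbent <- factor(df$sorbent, levels = design$sorbents)
  structure(df, design = design,
            class = c("measurement_table", "data.frame"))
}

#' Read a tidy measurement CSV
#'
#' Reads an RFC-4180 CSV with header columns
#' `contaminant,sorbent,replicate,response,value` and validates it against a
#' design via [measurement_table()].
#'
#' @param path Path to the CSV file.
#' @inheritParams measurement_table
#' @return A `"measurement_table"`.
#' @export
read_measurements <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  measurement_table(df, design)
}

#' Per-cell treatment means of one response
#'
#' Averages replicates within each (sorbent, contaminant) cell.
#'
#' @param x A `"measurement_table"`.
#' @param response Response name present in the table.
#' @return A numeric matrix, sorbents in rows, contaminants in columns, in
#'   design order.
#' @export
cell_means <- function(x, response) {
  stopifnot(inherits(x, "measurement_table"))
  sub <- x[x$response == response, ]
  if (!nrow(sub))
    stop("response '", response, "' not present in table", call. = FALSE)
  tapply(sub$value, list(sub$sorbent, sub$contaminant), mean)
}

#' Convert a wide treatment sheet to tidy long form
#'
#' Helper for sheets laid out the way factorial results are usually printed:
#' one row per sorbent, one column per contaminant.
#'
#' @param df Data.frame whose first column holds sorbent labels and whose
#'   remaining columns are contaminant levels.
#' @param response Response name to assign to all values.
#' @param replicate Replicate id to assign (wide sheets carry cell means, so
#'   this defaults to 1).
#' @return A tidy data.frame with the [measurement_table()] columns.
#' @export
wide_to_long <- function(df, response, replicate = 1L) {
  df <- as.data.frame(df)
  sorbent <- as.character(df[[1]])
  metals <- names(df)[-1]
  data.frame(
    contaminant = rep(metals, each = nrow(df)),
    sorbent = rep(sorbent, times = length(metals)),
    replicate = as.integer(replicate),
    response = response,
    value = as.numeric(unlist(df[-1], use.names = FALSE)),
    stringsAsFactors = FALSE)
}

#' @export
print.measurement_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Measurement table: %d rows, %d response(s) [%s]\n",
              nrow(x), length(unique(x$response)),
              paste(unique(x$response), collapse = ", ")))
  NextMethod()
}
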