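#' Compress a letter string into range notation
#'
#' Renders homogeneous-group letters the way factorial result tables print
#' them: consecutive alphabet runs are collapsed to their endpoints, so
#' `"defgh"` becomes `"d-h"` and `"abde"` becomes `"ab,d-e"` stays `"abd-e"`.
#'
#' @param x Character vector of concatenated single letters.
#' @return Character vector with runs of 3+ letters collapsed to `"x-y"`.
#' @export
#' @examples
#' format_letter_runs("defgh")
format_letter_runs <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    idx <- match(strsplit(s, "")[[1]], letters)
    if (anyNA(idx)) return(s)  # multi-char labels: leave untouched
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    paste(vapply(runs, function(r) {
      if (length(r) >= 3) paste0(letters[r[1]], "-", letters[r[length(r)]])
      else paste(letters[r], collapse = "")
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Recompute the published numbers of the greenhouse study
#'
#' Recomputes, from the shipped cell-mean fixtures alone, (i) every published
#' metal/sorbent impact percentage and (ii) every published marginal
#' "Average" cell, and compares them with the printed values. Impact
#' percentages are compared at half a unit of their printed precision
#' (0.05 percentage points for 1-decimal values, 0.005 for 2-decimal
#' values). Marginal means are compared at one unit of the printed
#' precision, the worst-case discrepancy from averaging cells that were
#' themselves rounded before printing. The function is read-only on the
#' fixtures.
#'
#' @return Data.frame of class `"reference_check"` with columns `check`,
#'   `response`, `label`, `computed`, `printed`, `diff`, `tol`, `pass`.
#' @export
#' @examples
#' chk <- verify_reference_values()
#' summary(chk$pass)
verify_reference_values <- function() {
  fam_of <- c(Org = "microbial", Act = "microbial", Fun = "microbial",
              Deh = "enzymes", Cat = "enzymes", Ure = "enzymes",
              Pac = "enzymes", Pal = "enzymes", Aryl = "enzymes",
              Glu = "enzymes", Shoots = "yield", Roots = "yield",
              SPAD = "spad")
  tabs <- lapply(unique(fam_of), greenhouse_measurements)
  names(tabs) <- unique(fam_of)

  ref <- greenhouse_reference_effects()
  eff <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    ifm <- index_matrices(tabs[[fam_of[r$response]]], r$response,
                          percent = TRUE)
    computed <- ifm[[r$index]][r$sorbent, r$contaminant]
    dec <- if (round(r$printed_pct, 1) == r$printed_pct) 1L else 2L
    tol <- 0.5 * 10^-dec
    data.frame(check = "impact_pct", response = r$response,
               label = sprintf("%s(%s, %s)", r$index, r$contaminant,
                               r$sorbent),
               computed = computed, printed = r$printed_pct,
               diff = abs(computed - r$printed_pct), tol = tol,
               pass = abs(computed - r$printed_pct) <= tol + 1e-9,
               stringsAsFactors = FALSE)
  }))

  marg <- greenhouse_marginal_means()
  mar <- do.call(rbind, lapply(seq_len(nrow(marg)), function(i) {
    r <- marg[i, ]
    mu <- cell_means(tabs[[r$family]], r$response)
    computed <- if (r$margin == "sorbent") mean(mu[r$level, ])
                else mean(mu[, r$level])
    dec <- if (r$family == "enzymes") 3L else 2L
    tol <- 10^-dec  # one printed ULP: cell rounding + print rounding
    data.frame(check = "marginal_mean", response = r$response,
               label = sprintf("%s margin, %s", r$margin, r$level),
               computed = computed, printed = r$printed,
               diff = abs(computed - r$printed), tol = tol,
               pass = abs(computed - r$printed) <= tol + 1e-9,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(eff, mar)
  class(out) <- c("reference_check", "data.frame")
  out
}

#' @export
print.reference_check <- function(x, digits = 4, ...) {
  for (what in unique(x$check)) {
    sub <- x[x$check == what, ]
    cat(sprintf("%s: %d/%d recomputed within tolerance\n",
                what, sum(sub$pass), nrow(sub)))
    bad <- sub[!sub$pass, ]
    if (nrow(bad)) {
      cat("  outside tolerance:\n")
      for (i in seq_len(nrow(bad)))
        cat(sprintf("    %s %s: computed %.4g vs printed %.4g (tol %.3g)\n",
                    bad$response[i], bad$label[i], bad$computed[i],
                    bad$printed[i], bad$tol[i]))
    }
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end run: load or generate a measurement table,
#' compute metal and sorbent impact matrices per response (written as CSV,
#' optionally rendered as clustered heat maps), fit the two-way ANOVA with
#' eta-squared shares and letter displays where replicates allow it
#' (JSON + CSV), run the Pearson correlation screen and PCA across
#' responses on the cell-mean matrix, optionally generate emergence plates
#' and their CD/EP table, and write a manifest of every artifact with input
#' hashes and the seed.
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{`list(type = "fixture", family = ...)`,
#'       `list(type = "csv", path = ..., replicates = ...)`, or
#'       `list(type = "synthetic", config = generator_config())`.}
#'     \item{responses}{Responses to analyse; default all present. Must
#'       select at least one.}
#'     \item{alpha}{Significance level, in (0, 1); default 0.05.}
#'     \item{out_dir}{Output directory, created if needed.}
#'     \item{precision}{Decimals for percent formatting in reports
#'       (default 1).}
#'     \item{clustering}{`list(distance = , linkage = )` for the heat maps.}
#'     \item{heatmaps}{Render heat-map PNGs (default TRUE).}
#'     \item{emergence_plates}{Plates of synthetic emergence data to add
#'       (default 0; synthetic input only).}
#'     \item{seed}{Seed for synthetic stages.}
#'   }
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("config error: 'alpha' must lie in (0, 1)", call. = FALSE)
  out_dir <- config$out_dir %||% stop("config error: 'out_dir' is required",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  precision <- config$precision %||% 1
  clus <- config$clustering %||% list()
  distance <- clus$distance %||% "euclidean"
  linkage <- clus$linkage %||% "complete"
  heatmaps <- config$heatmaps %||% TRUE
  seed <- config$seed

  input <- config$input %||% stop("config error: 'input' is required",
                                  call. = FALSE)
  input_hash <- NULL
  gen_cfg <- NULL
  tab <- switch(input$type %||% stop("config error: input$type missing",
                                     call. = FALSE),
    fixture = {
      path <- system.file("extdata",
                          paste0("greenhouse_", input$family, ".csv"),
                          package = "soilsorb", mustWork = TRUE)
      input_hash <- unname(tools::md5sum(path))
      greenhouse_measurements(input$family)
    },
    csv = {
      reps <- input$replicates %||% c(default = 3L)
      if (is.null(names(reps))) names(reps) <- rep("default", length(reps))
      input_hash <- unname(tools::md5sum(input$path))
      read_measurements(input$path, greenhouse_design(replicates = reps))
    },
    synthetic = {
      gen_cfg <- input$config %||% generator_config(seed = seed)
      generate_measurements(gen_cfg, seed = seed %||% gen_cfg$seed)
    },
    stop("config error: unknown input type '", input$type, "'",
         call. = FALSE))

  responses <- config$responses %||% unique(tab$response)
  if (!length(responses))
    stop("config error: at least one response must be selected",
         call. = FALSE)
  missing_resp <- setdiff(responses, unique(tab$response))
  if (length(missing_resp))
    stop("config error: response(s) not in input: ",
         paste(missing_resp, collapse = ", "), call. = FALSE)

  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  msg <- function(...) message("[soilsorb] ", sprintf(...))

  for (resp in responses) {
    msg("indices: %s", resp)
    ifm <- index_matrices(tab, resp)
    for (kind in names(ifm)) {
      f <- file.path(out_dir, sprintf("%s_%s.csv", kind, resp))
      write_index_matrix(ifm[[kind]], f); add(f)
      if (heatmaps) {
        hf <- file.path(out_dir, sprintf("%s_%s_heatmap.png", kind, resp))
        cluster_heatmap(unclass(ifm[[kind]]), file = hf,
                        distance = distance, linkage = linkage)
        add(hf)
      }
    }
    n_cell <- table(tab$contaminant[tab$response == resp],
                    tab$sorbent[tab$response == resp])
    if (min(n_cell) >= 2) {
      msg("anova: %s", resp)
      fit <- ms_anova(tab, resp, alpha = alpha)
      rep_list <- list(response = resp,
                       anova = fit$anova_table,
                       eta2_pct = as.list(fit$eta2),
                       alpha = alpha)
      f <- file.path(out_dir, sprintf("anova_%s.json", resp))
      jsonlite::write_json(rep_list, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      add(f)
      for (lev in names(fit$letters)) {
        cld <- as.data.frame(fit$letters[[lev]])
        cld$letters_compact <- format_letter_runs(cld$letters)
        f <- file.path(out_dir, sprintf("letters_%s_%s.csv", resp, lev))
        utils::write.csv(cld, f, row.names = FALSE); add(f)
      }
    } else msg("anova skipped for %s: single replicate per cell", resp)
  }

  if (length(responses) >= 2) {
    msg("correlation + PCA across %d responses", length(responses))
    wide <- sapply(responses, function(r) as.vector(cell_means(tab, r)))
    corr <- pearson_matrix(wide, alpha = alpha)
    f <- file.path(out_dir, "correlation.json")
    jsonlite::write_json(list(r = corr$r, p = corr$p, n = corr$n,
                              alpha = alpha, variables = responses),
                         f, digits = NA, matrix = "rowmajor")
    add(f)
    pca <- ms_pca(wide)
    f <- file.path(out_dir, "pca_loadings.csv")
    utils::write.csv(data.frame(variable = responses, pca$loadings),
                     f, row.names = FALSE); add(f)
    f <- file.path(out_dir, "pca_scores.csv")
    utils::write.csv(data.frame(case = seq_len(nrow(pca$scores)),
                                pca$scores, check.names = FALSE),
                     f, row.names = FALSE); add(f)
    f <- file.path(out_dir, "pca_explained_pct.csv")
    utils::write.csv(data.frame(component = seq_along(pca$sdev),
                                explained_pct = pca$explained_variance_pct),
                     f, row.names = FALSE); add(f)
  }

  n_plates <- config$emergence_plates %||% 0
  if (n_plates > 0) {
    if (is.null(gen_cfg)) gen_cfg <- generator_config(seed = seed)
    msg("emergence: %d synthetic plates", n_plates)
    plates <- generate_emergence(gen_cfg, n_plates,
                                 seed = (seed %||% 0) + 1)
    idx <- colony_indices(plates)
    f <- file.path(out_dir, "colony_indices.csv")
    utils::write.csv(idx, f, row.names = FALSE); add(f)
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = input[setdiff(names(input), "config")],
    input_md5 = input_hash, seed = seed, alpha = alpha,
    responses = responses, precision = precision,
    clustering = list(distance = distance, linkage = linkage),
    artifacts = lapply(artifacts, function(a)
      list(path = a, md5 = unname(tools::md5sum(a)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
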