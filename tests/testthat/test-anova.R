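make_balanced <- function(k_a = 4, k_b = 7, reps = 3, seed = 1,
                          fun = function(a, b) rnorm(1)) {
  set.seed(seed)
  d <- experiment_design(paste0("A", seq_len(k_a)), paste0("B", seq_len(k_b)),
                         replicates = c(x = as.integer(reps)))
  grid <- expand.grid(contaminant = d$contaminants, sorbent = d$sorbents,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  grid$response <- "y"
  grid$value <- mapply(fun, grid$contaminant, grid$sorbent) +
    rnorm(nrow(grid), sd = 1)
  list(design = d, tab = measurement_table(grid, d))
}

test_that("a pure one-factor signal loads the whole SS on that factor", {
  d <- experiment_design(c("A1", "A2"), c("B1", "B2"),
                         replicates = c(x = 2L))
  df <- data.frame(
    contaminant = rep(c("A1", "A2"), each = 4),
    sorbent = rep(c("B1", "B2", "B1", "B2"), each = 2),
    replicate = rep(1:2, 4), response = "y",
    value = c(0, 0, 0, 0, 10, 10, 10, 10))
  # a zero-residual fit makes stats::anova warn about unreliable F-tests;
  # only the SS decomposition is under test here
  fit <- suppressWarnings(ms_anova(measurement_table(df, d), "y"))
  tab <- fit$anova_table
  expect_equal(tab$SS[tab$term == "contaminant"], sum(tab$SS))
  expect_equal(unname(fit$eta2["contaminant"]), 100)
  expect_equal(unname(fit$eta2["error"]), 0)
  expect_lt(tab$p[tab$term == "contaminant"], 1e-10)
})

test_that("SS terms match the brute-force mean-decomposition oracle", {
  for (seed in 1:5) {
    x <- make_balanced(4, 7, 3, seed = seed,
                       fun = function(a, b) 2 * (a == "A2") - (b == "B3"))
    fit <- ms_anova(x$tab, "y")
    got <- stats::setNames(fit$anova_table$SS, fit$anova_table$term)
    want <- oracle_ss(x$tab[x$tab$response == "y", ])
    for (term in c("contaminant", "sorbent", "interaction", "error"))
      expect_equal(unname(got[term]), unname(want[term]), tolerance = 1e-9)
    # additivity, eta2 partition, df sum
    expect_equal(sum(got), unname(want["total"]), tolerance = 1e-9)
    expect_equal(sum(fit$eta2), 100, tolerance = 1e-9)
    expect_equal(sum(fit$anova_table$df), nrow(x$tab) - 1)
  }
})

test_that("unbalanced or unreplicated tables are rejected", {
  x <- make_balanced(2, 2, 3, seed = 3)
  sub <- as.data.frame(x$tab)
  unbal <- sub[-1, ]
  expect_error(ms_anova(unbal, "y", design = x$design), "design-mismatch")
  # manual bypass of table validation still trips the balance check
  tab_unbal <- x$tab[-1, ]
  attr(tab_unbal, "design") <- x$design
  class(tab_unbal) <- class(x$tab)
  expect_error(ms_anova(tab_unbal, "y"), "balance error")

  one_rep <- greenhouse_measurements("microbial")
  expect_error(ms_anova(one_rep, "Org"), "balance error")
})

test_that("fit methods are mutually consistent", {
  x <- make_balanced(3, 4, 3, seed = 11,
                     fun = function(a, b) (a == "A1") * 1.5)
  fit <- ms_anova(x$tab, "y")
  expect_equal(dim(coef(fit)), c(4, 3))  # sorbents x contaminants
  expect_equal(fitted(fit) + residuals(fit), x$tab$value[x$tab$response == "y"])
  expect_equal(sum(residuals(fit)^2),
               fit$anova_table$SS[fit$anova_table$term == "error"],
               tolerance = 1e-9)
  pred <- predict(fit, data.frame(contaminant = "A1", sorbent = "B2"))
  expect_equal(unname(pred), coef(fit)["B2", "A1"])
  expect_error(predict(fit, data.frame(contaminant = "A9", sorbent = "B2")),
               "level error")

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "measurement_table")
  expect_equal(nrow(sims[[1]]), nrow(fit$data))
  # refitting a simulated table preserves the design shape
  refit <- ms_anova(sims[[1]], "y")
  expect_equal(dim(coef(refit)), dim(coef(fit)))
})
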