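test_that("day profiles normalise counts and reject empty plates", {
  expect_equal(as.numeric(day_profile(c(5, 5, rep(0, 8)))),
               c(0.5, 0.5, rep(0, 8)))
  expect_equal(as.numeric(day_profile(rep(10, 10))), rep(0.1, 10))
  expect_error(day_profile(rep(0, 10)), "undefined index")
  expect_error(emergence_series(c(-1, 2)), "non-negative")
  expect_error(emergence_series(c(1.5, 2)), "non-negative")
})

test_that("CD attains its exact bounds and the uniform-profile value", {
  expect_equal(colony_development(c(1, rep(0, 9))), 100)
  expect_equal(colony_development(c(rep(0, 9), 1)), 10)
  # uniform profile: 10 * sum of 1/d over ten days
  expect_equal(colony_development(rep(1, 10)), 10 * sum(1 / (1:10)),
               tolerance = 1e-14)
  expect_equal(colony_development(rep(1, 10)), 29.28968254,
               tolerance = 1e-8)
})

test_that("EP attains its exact bounds and the two-day split value", {
  expect_equal(ecophysiological_diversity(c(7, rep(0, 9))), 0)
  expect_equal(ecophysiological_diversity(rep(3, 10)), 1)
  expect_equal(ecophysiological_diversity(c(5, 5, rep(0, 8))),
               0.3010299957, tolerance = 1e-9)
})

test_that("CD and EP stay in bounds, are scale invariant, and match loop oracles", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- random_counts(10)
    cd <- colony_development(counts)
    ep <- ecophysiological_diversity(counts)
    expect_gte(cd, 10); expect_lte(cd, 100)
    expect_gte(ep, 0); expect_lte(ep, 1 + 1e-12)
    expect_equal(cd, oracle_cd(counts), tolerance = 1e-12)
    expect_equal(ep, oracle_ep(counts), tolerance = 1e-12)
  }
  counts <- random_counts(10)
  for (c_mult in c(2L, 7L)) {
    expect_equal(colony_development(counts * c_mult),
                 colony_development(counts), tolerance = 1e-14)
    expect_equal(ecophysiological_diversity(counts * c_mult),
                 ecophysiological_diversity(counts), tolerance = 1e-14)
  }
})

test_that("impact factor reproduces reference cases and its swap identity", {
  # Cu suppression of organotrophic bacteria in unamended soil
  expect_equal(impact_factor(26.42, 30.62), -0.1372, tolerance = 1e-3)
  # zeolite stimulation of actinomycetes under Zn
  expect_equal(impact_factor(32.44, 10.45), 2.1043, tolerance = 1e-4)
  expect_equal(impact_factor(7, 7), 0)
  expect_error(impact_factor(1, 0), "undefined reference")
  expect_error(impact_factor(-1, 2), "non-negative")

  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50)
    f <- impact_factor(a, b); g <- impact_factor(b, a)
    expect_equal(f, -g / (1 + g), tolerance = 1e-12)
  }
})

test_that("index matrices use the right references and reproduce table-derived cells", {
  tab <- greenhouse_measurements("microbial")
  ifm <- index_matrices(tab, "Org")
  expect_equal(unname(ifm$IF_Ad["Molecular sieve", "Ni"]),
               37.86 / 24.85 - 1, tolerance = 1e-12)
  expect_equal(unname(ifm$IF_Ad["Molecular sieve", "Ni"]), 0.524,
               tolerance = 1e-3)
  yld <- greenhouse_measurements("yield")
  ifm_y <- index_matrices(yld, "Shoots")
  expect_equal(unname(ifm_y$IF_HM["Control", "Ni"]), -0.536,
               tolerance = 1e-3)
  # undefined reference lines
  expect_true(all(is.na(ifm$IF_HM[, "C0"])))
  expect_true(all(is.na(ifm$IF_Ad["Control", ])))
  expect_false(anyNA(ifm$IF_HM[, -1]))

  # constant table: both matrices identically zero
  d <- greenhouse_design(replicates = c(mean = 1L))
  const <- expand.grid(contaminant = d$contaminants, sorbent = d$sorbents,
                       stringsAsFactors = FALSE)
  const$replicate <- 1L; const$response <- "Org"; const$value <- 7.0
  ifc <- index_matrices(measurement_table(const, d), "Org")
  expect_true(all(ifc$IF_HM[!is.na(ifc$IF_HM)] == 0))
  expect_true(all(ifc$IF_Ad[!is.na(ifc$IF_Ad)] == 0))

  # zero reference mean is an error naming the cell
  zero <- const; zero$value[zero$contaminant == "C0" &
                              zero$sorbent == "Control"] <- 0
  expect_error(index_matrices(measurement_table(zero, d), "Org"),
               "undefined reference")
})

test_that("colony_indices summarises plates and flags empty ones", {
  plates <- list(emergence_series(c(10, rep(0, 9)), group = "Org"),
                 emergence_series(rep(0, 10), group = "Org"))
  expect_warning(idx <- colony_indices(plates), "empty plate")
  expect_equal(idx$CD[1], 100)
  expect_true(is.na(idx$CD[2]) && is.na(idx$EP[2]))
})
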