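test_that("generator configuration is validated", {
  expect_error(generator_config(cv = 0), "cv")
  expect_error(generator_config(cv = 0.6), "cv")
  expect_error(generator_config(metal_effect = list(Org = c(Cu = -1))),
               "positive")
  expect_error(generator_config(metal_effect = list(Org = c(C0 = 2))),
               "reference")
  expect_error(generator_config(metal_effect = list(Org = c(Pb = 2))),
               "unknown")
  expect_error(generator_config(emergence_alpha = rep(0, 10)), "positive")
  expect_error(generator_config(emergence_alpha = rep(1, 3)), "length")
})

test_that("generation is seed-deterministic and has the design-forced shape", {
  cfg <- generator_config(seed = 123)
  t1 <- generate_measurements(cfg)
  t2 <- generate_measurements(cfg)
  expect_identical(t1$value, t2$value)          # bit-identical given seed
  expect_equal(nrow(t1), 4 * 7 * 4)             # microbial: 4 reps x 28 cells

  e1 <- generate_emergence(cfg, 5)
  e2 <- generate_emergence(cfg, 5)
  expect_identical(lapply(e1, `[[`, "counts"), lapply(e2, `[[`, "counts"))
})

test_that("the noise-free limit recovers the configured cell structure", {
  cfg <- generator_config(
    baseline = c(Org = 30),
    metal_effect = list(Org = c(Ni = 0.8)),
    sorbent_effect = list(Org = c(Zeolite = 1.5)),
    cv = 1e-6, seed = 4)
  tab <- generate_measurements(cfg)
  mu <- cell_means(tab, "Org")
  expect_equal(unname(mu["Control", "C0"]), 30, tolerance = 1e-4)
  expect_equal(unname(mu["Control", "Ni"]), 24, tolerance = 1e-4)
  expect_equal(unname(mu["Zeolite", "C0"]), 45, tolerance = 1e-4)
  expect_equal(unname(mu["Zeolite", "Ni"]), 36, tolerance = 1e-4)
  ifm <- index_matrices(tab, "Org")
  expect_equal(unname(ifm$IF_HM["Control", "Ni"]), -0.2, tolerance = 1e-4)
  expect_equal(unname(ifm$IF_Ad["Zeolite", "C0"]), 0.5, tolerance = 1e-4)
})

test_that("scaling all baselines rescales values and leaves indices untouched", {
  cfg1 <- generator_config(baseline = c(Org = 30), seed = 9)
  cfg2 <- generator_config(baseline = c(Org = 300), seed = 9)
  t1 <- generate_measurements(cfg1)
  t2 <- generate_measurements(cfg2)
  expect_equal(t2$value, 10 * t1$value, tolerance = 1e-12)
  i1 <- index_matrices(t1, "Org"); i2 <- index_matrices(t2, "Org")
  expect_equal(unclass(i1$IF_HM), unclass(i2$IF_HM), tolerance = 1e-12)
  expect_equal(unclass(i1$IF_Ad), unclass(i2$IF_Ad), tolerance = 1e-12)
})

test_that("emergence profiles follow the configured concentration", {
  D <- 10
  cfg <- generator_config(
    emergence_alpha = c(1e6, rep(1e-3, D - 1)),
    total_colonies_mean = 100, seed = 10)
  plates <- generate_emergence(cfg, 20)
  cds <- vapply(plates, function(p) colony_development(p$counts), numeric(1))
  expect_true(all(cds > 99.9))  # essentially all colonies on day 1

  # symmetric concentration: mean EP close to its Monte-Carlo expectation
  cfg_sym <- generator_config(emergence_alpha = rep(5, D),
                              total_colonies_mean = 200, seed = 11)
  plates <- generate_emergence(cfg_sym, 500)
  ep_hat <- mean(vapply(plates, function(p)
    ecophysiological_diversity(p$counts), numeric(1)))
  # independent oracle: direct simulation of the Dirichlet-multinomial EP
  set.seed(77)
  ep_mc <- mean(replicate(4000, {
    g <- rgamma(D, 5); p <- g / sum(g)
    n <- rpois(1, 200)
    counts <- if (n > 0) as.vector(rmultinom(1, n, p)) else
      c(1, rep(0, D - 1))
    pr <- counts / sum(counts); pr <- pr[pr > 0]
    -sum(pr * log10(pr))
  }))
  expect_equal(ep_hat, ep_mc, tolerance = 0.05)

  # near-zero colony totals leave most plates empty
  cfg0 <- generator_config(total_colonies_mean = 0.001, seed = 12)
  plates <- generate_emergence(cfg0, 10)
  expect_true(any(vapply(plates, function(p) sum(p$counts) == 0, logical(1))))
  expect_error(day_profile(plates[[1]]$counts), "undefined index")
})

test_that("small recovery runs are unbiased and well powered", {
  # known metal effect 0.8 -> true IF_HM = -0.2
  cfg <- generator_config(baseline = c(Org = 30),
                          metal_effect = list(Org = c(Ni = 0.8)),
                          sorbent_effect = list(), cv = 0.05, seed = 14)
  rec <- recovery_experiment(cfg, n_sim = 200)
  expect_equal(mean(rec$if_hm$estimate[, "Ni"]), -0.2, tolerance = 0.01)
  expect_equal(rec$letter_violations, 0L)
  # a 20% suppression at cv = 0.05 with 4 replicates is always detected
  expect_gt(unname(rec$rejection_rate["contaminant"]), 0.95)

  # strong sorbent effect at cv = 0.1: high power on the sorbent term
  cfg2 <- generator_config(baseline = c(Org = 30),
                           metal_effect = list(),
                           sorbent_effect = list(Org = c(Zeolite = 1.5)),
                           cv = 0.1, seed = 15)
  rec2 <- recovery_experiment(cfg2, n_sim = 100, check_letters = FALSE)
  expect_gt(unname(rec2$rejection_rate["sorbent"]), 0.95)
})
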