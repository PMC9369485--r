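test_that("Pearson screen reproduces exact and degenerate cases", {
  set.seed(5)
  x <- rnorm(20)
  m <- cbind(x = x, self = x, neg = -x, noise = rnorm(20))
  rep_ <- pearson_matrix(m)
  expect_equal(unname(rep_$r["x", "self"]), 1)
  expect_true(rep_$significant["x", "self"])
  expect_equal(unname(rep_$r["x", "neg"]), -1)
  expect_equal(rep_$n, 20)
  expect_error(pearson_matrix(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance.*a")
  expect_error(pearson_matrix(m[1:2, ]), "at least 3")
})

test_that("correlation detection is reliable at rho = 0.5, n = 112", {
  in_band <- logical(200); flagged <- logical(200)
  for (s in 1:200) {
    set.seed(s)
    z <- rnorm(112)
    x <- z
    y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(112)
    rep_ <- pearson_matrix(cbind(x = x, y = y))
    in_band[s] <- abs(rep_$r["x", "y"] - 0.5) <= 0.2
    flagged[s] <- rep_$significant["x", "y"]
  }
  expect_gte(mean(flagged), 0.99)
  expect_gte(mean(in_band), 0.95)
})

test_that("PCA standardises, orders components, and reconstructs", {
  set.seed(8)
  x <- rnorm(50)
  two <- cbind(a = x, b = 2 * x + 3)  # perfectly correlated pair
  pc <- ms_pca(two)
  expect_equal(pc$explained_variance_pct[1], 100, tolerance = 1e-9)

  m <- matrix(rnorm(50 * 4), ncol = 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  pc <- ms_pca(m)
  expect_equal(sum(pc$explained_variance_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(pc$sdev) <= 1e-12))           # non-increasing variance
  expect_equal(crossprod(pc$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)                    # orthonormal loadings
  # scores %*% t(loadings) reproduces the standardised data
  z <- scale(m)
  expect_equal(pc$scores %*% t(pc$loadings), z, tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign anchor: largest-magnitude loading of each column is positive
  anchors <- apply(pc$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(anchors > 0))
  # permutation invariance of explained variance
  pc_perm <- ms_pca(m[, c(3, 1, 4, 2)])
  expect_equal(pc_perm$explained_variance_pct, pc$explained_variance_pct,
               tolerance = 1e-9)
  expect_error(ms_pca(cbind(a = rep(2, 10), b = rnorm(10))), "zero-variance")
})

test_that("isotropic noise spreads explained variance evenly", {
  set.seed(21)
  m <- matrix(rnorm(3e4), ncol = 3)
  pc <- ms_pca(m)
  expect_equal(pc$explained_variance_pct, rep(100 / 3, 3), tolerance = 0.06)
})

test_that("heatmap clustering matches a brute-force agglomeration oracle", {
  set.seed(13)
  m <- matrix(rnorm(28), nrow = 7,
              dimnames = list(paste0("r", 1:7), paste0("c", 1:4)))
  res <- cluster_heatmap(m)
  expect_equal(sort(res$row_hclust$height),
               sort(oracle_complete_linkage_heights(m)), tolerance = 1e-9)
  expect_equal(sort(res$col_hclust$height),
               sort(oracle_complete_linkage_heights(t(m))), tolerance = 1e-9)

  # identical rows merge first, at height zero, as adjacent leaves
  m2 <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  colnames(m2) <- c("x", "y")
  res2 <- cluster_heatmap(m2)
  expect_equal(res2$row_hclust$height[1], 0)
  pos <- match(c("a", "b"), res2$row_order)
  expect_equal(abs(diff(pos)), 1)
  # the outlier joins in the final merge
  expect_equal(max(res2$row_hclust$height),
               as.numeric(dist(rbind(c(0, 0), c(10, 10)))))

  # single row: clustering skipped, input order preserved
  res3 <- cluster_heatmap(m[1, , drop = FALSE])
  expect_null(res3$row_hclust)
  expect_equal(res3$row_order, "r1")

  # all-NA reference lines are dropped (impact-matrix layout)
  m4 <- m; m4[, 1] <- NA
  res4 <- cluster_heatmap(m4)
  expect_equal(res4$col_order %in% colnames(m)[-1], rep(TRUE, 3))
})
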