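# Independent oracles used across the suite. All deliberately naive:
# explicit loops and enumeration, no shared code with the package internals.

# CD/EP by term-by-term loop summation over a count vector
oracle_cd <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (d in seq_along(counts)) acc <- acc + (counts[d] / total) / d
  100 * acc
}
oracle_ep <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (d in seq_along(counts)) {
    p <- counts[d] / total
    if (p > 0) acc <- acc - p * log10(p)
  }
  acc
}

# Brute-force balanced two-way SS decomposition from cell/marginal means
oracle_ss <- function(df) {
  A <- unique(as.character(df$contaminant))
  B <- unique(as.character(df$sorbent))
  grand <- mean(df$value)
  r <- nrow(df) / (length(A) * length(B))
  ss_a <- 0
  for (a in A) {
    m <- mean(df$value[df$contaminant == a])
    ss_a <- ss_a + length(B) * r * (m - grand)^2
  }
  ss_b <- 0
  for (b in B) {
    m <- mean(df$value[df$sorbent == b])
    ss_b <- ss_b + length(A) * r * (m - grand)^2
  }
  ss_ab <- 0; ss_err <- 0
  for (a in A) for (b in B) {
    idx <- df$contaminant == a & df$sorbent == b
    cm <- mean(df$value[idx])
    ma <- mean(df$value[df$contaminant == a])
    mb <- mean(df$value[df$sorbent == b])
    ss_ab <- ss_ab + r * (cm - ma - mb + grand)^2
    ss_err <- ss_err + sum((df$value[idx] - cm)^2)
  }
  c(contaminant = ss_a, sorbent = ss_b, interaction = ss_ab,
    error = ss_err, total = sum((df$value - grand)^2))
}

# Monte-Carlo studentized range: draws of (max-min of k std normal means,
# scaled by an independent chi-square sd estimate on df degrees of freedom)
oracle_qtukey_draws <- function(n_draws, k, df) {
  z <- matrix(rnorm(n_draws * k), ncol = k)
  s <- sqrt(rchisq(n_draws, df) / df)
  (apply(z, 1, max) - apply(z, 1, min)) / s
}

# Exhaustive minimal letter display: cover every non-significant pair and
# every item with the fewest cliques of the non-significance graph such
# that no clique contains a significant pair.
oracle_min_letters <- function(p, alpha) {
  k <- nrow(p)
  nonsig <- p >= alpha
  diag(nonsig) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s)
    all(nonsig[s, s, drop = FALSE]), logical(1))
  cliques <- subsets[is_clique]
  edges <- which(nonsig & upper.tri(nonsig), arr.ind = TRUE)
  covers <- function(sel) {
    cl <- cliques[sel]
    verts <- unique(unlist(cl))
    if (length(verts) < k) return(FALSE)
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (!any(vapply(cl, function(s) i %in% s && j %in% s, logical(1))))
          return(FALSE)
      }
    }
    TRUE
  }
  for (m in 1:k) {
    combos <- utils::combn(length(cliques), m, simplify = FALSE)
    for (sel in combos) if (covers(sel)) return(m)
  }
  k
}

# Direct O(n^3) agglomerative clustering (complete linkage), returns the
# sequence of merge heights
oracle_complete_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# shared-letter predicate on a letter_display (single-char labels)
cld_share <- function(cld, a, b) {
  la <- strsplit(cld$letters[cld$level == a], "")[[1]]
  lb <- strsplit(cld$letters[cld$level == b], "")[[1]]
  length(intersect(la, lb)) > 0
}

# random valid emergence count vector (at least one colony)
random_counts <- function(D = 10) {
  repeat {
    x <- rpois(D, lambda = runif(1, 0.5, 30))
    if (sum(x) > 0) return(x)
  }
}
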