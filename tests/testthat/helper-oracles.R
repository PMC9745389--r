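# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Random non-ultrametric tree with uniform branch lengths.
rand_tree <- function(n, min_bl = 0.1, max_bl = 2) {
  phy <- ape::rtree(n, br = function(k) stats::runif(k, min_bl, max_bl))
  phy
}

# Random ultrametric tree.
rand_ultra <- function(n) ape::rcoal(n)

# Dense multivariate-normal maximized log-likelihood: GLS mean, profiled
# sigma2, log-determinant by dense factorization. R is the unit-rate
# correlation/structure matrix.
dense_lnl <- function(R, y) {
  n <- length(y)
  Ri <- solve(R)
  z0 <- sum(Ri %*% y) / sum(Ri)
  q <- drop(t(y - z0) %*% Ri %*% (y - z0))
  s2 <- q / n
  -0.5 * (n * (log(2 * pi * s2) + 1) +
            determinant(R, logarithm = TRUE)$modulus[1])
}

# Recursive equal-splits oracle: apportion each edge equally at every split
# walking root -> tip (s_child = s_parent / 2 + edge), the opposite
# direction from the implementation's per-tip path sum.
es_oracle <- function(phy) {
  n <- length(phy$tip.label)
  es <- numeric(n)
  walk <- function(node, s) {
    kid_edges <- which(phy$edge[, 1] == node)
    for (k in kid_edges) {
      ch <- phy$edge[k, 2]
      s2 <- s / 2 + phy$edge.length[k]
      if (ch <= n) es[ch] <<- s2 else walk(ch, s2)
    }
  }
  walk(n + 1L, 0)
  stats::setNames(es, phy$tip.label)
}

# Conditional-expectation matrix formula for ancestral states under the
# lambda model: dense covariance algebra on the transformed tree.
asr_matrix_oracle <- function(phy, y, lambda = 1) {
  n <- length(phy$tip.label)
  tphy <- phy
  if (lambda != 1) {
    d <- ape::node.depth.edgelength(phy)[seq_len(n)]
    el <- phy$edge.length * lambda
    term <- phy$edge[, 2] <= n
    el[term] <- el[term] + (1 - lambda) * d[phy$edge[term, 2]]
    tphy$edge.length <- el
  }
  V <- ape::vcv.phylo(tphy)
  depth <- ape::node.depth.edgelength(tphy)
  M <- ape::mrca(tphy, full = TRUE)
  Vi <- solve(V)
  y <- y[phy$tip.label]
  z0 <- sum(Vi %*% y) / sum(Vi)
  vapply((n + 1L):(n + phy$Nnode), function(nd) {
    cv <- depth[M[nd, seq_len(n)]]
    z0 + drop(cv %*% Vi %*% (y - z0))
  }, numeric(1))
}

# Brute-force species-to-bin assignment by scalar double loop.
membership_oracle <- function(summaries, bins, var) {
  mn <- summaries[[paste0("min_", var)]]
  mx <- summaries[[paste0("max_", var)]]
  out <- list()
  for (i in seq_len(nrow(bins))) {
    for (j in seq_len(nrow(summaries))) {
      closed <- i == nrow(bins)
      hit <- if (closed) {
        mx[j] >= bins$lower[i] && mn[j] <= bins$upper[i]
      } else {
        mx[j] >= bins$lower[i] && mn[j] < bins$upper[i]
      }
      if (hit) out[[length(out) + 1L]] <- c(i, summaries$species[j])
    }
  }
  df <- do.call(rbind, out)
  data.frame(bin = as.integer(df[, 1]), species = df[, 2],
             stringsAsFactors = FALSE)
}
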