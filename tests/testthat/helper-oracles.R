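# Independent brute-force oracles. Everything here is written from the
# defining formulas, deliberately avoiding the code paths (and packages) the
# implementation uses.

bf_shannon <- function(x, base = exp(1)) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

bf_chao1 <- function(x) {
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

bf_goods <- function(x) 1 - sum(x == 1) / sum(x)

bf_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

bf_bray_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- bf_bray(m[i, ], m[j, ])
  d
}

# Spearman rho from first principles: average ranks, then the Pearson
# product-moment formula written out.
bf_rank <- function(x) {
  sx <- sort(unique(x))
  r <- numeric(length(x))
  for (v in sx) {
    idx <- which(x == v)
    lo <- sum(x < v)
    r[idx] <- mean(lo + seq_along(idx))
  }
  r
}

bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_spearman <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

# Stepwise Benjamini-Hochberg: q_(i) = min over j >= i of p_(j) * m / j.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# ANOSIM R from the definition: rank all dissimilarities, compare mean
# between-group and within-group ranks.
bf_anosim_r <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  vals <- c(); within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  r <- bf_rank(vals)
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

bf_mantel_r <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  bf_pearson(a[upper.tri(a)], b[upper.tri(b)])
}

# betaMNTD by the naive double loop over community members.
bf_bmntd <- function(counts, dmat, weighted = TRUE) {
  n <- nrow(counts)
  out <- matrix(0, n, n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ta <- colnames(counts)[counts[a, ] > 0]
    tb <- colnames(counts)[counts[b, ] > 0]
    wa <- if (weighted) counts[a, ta] / sum(counts[a, ta]) else rep(1 / length(ta), length(ta))
    wb <- if (weighted) counts[b, tb] / sum(counts[b, tb]) else rep(1 / length(tb), length(tb))
    s1 <- 0
    for (k in seq_along(ta)) s1 <- s1 + wa[k] * min(dmat[ta[k], tb])
    s2 <- 0
    for (k in seq_along(tb)) s2 <- s2 + wb[k] * min(dmat[tb[k], ta])
    out[a, b] <- out[b, a] <- (s1 + s2) / 2
  }
  out
}

# --- graph oracles (adjacency-matrix algorithms) ----------------------------

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in 1:n) {
    for (v in order(d[s, ])) {
      if (is.finite(d[s, v]) && d[s, v] > 0) {
        preds <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  sigma
}

# Betweenness from the pair-dependency identity: v lies on a shortest s-t
# path iff d(s,v) + d(v,t) = d(s,t), contributing sigma_sv * sigma_vt /
# sigma_st. Ordered pairs counted, then halved (undirected).
bf_betweenness <- function(adj, normalized = FALSE) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  btw <- numeric(n)
  for (v in 1:n) for (s in 1:n) for (t in 1:n) {
    if (s != v && t != v && s != t && is.finite(d[s, t]) &&
        d[s, v] + d[v, t] == d[s, t]) {
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  btw <- btw / 2
  if (normalized) btw <- btw * 2 / ((n - 1) * (n - 2))
  btw
}

bf_local_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(1:n, function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  })
}

bf_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_in <- sum(adj[idx, idx]) / 2
    q <- q + e_in / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# --- small random generators -------------------------------------------------

random_counts <- function(n, k, lambda = 8) {
  m <- matrix(rpois(n * k, lambda), n, k,
              dimnames = list(paste0("S", seq_len(n)), paste0("O", seq_len(k))))
  m[rowSums(m) == 0, 1] <- 1L
  m
}

random_otu_table <- function(n, k, lambda = 8) otu_table(random_counts(n, k, lambda))

random_graph_adj <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

# Wrap an adjacency matrix as a cooc_network so the graph-metric surface can
# be exercised on arbitrary graphs.
network_from_adj <- function(adj, ids = paste0("O", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  pairs <- data.frame(otu_i = ids[idx[, 1]], otu_j = ids[idx[, 2]],
                      rho = 0.9, p = 1e-6, q = 1e-6,
                      stringsAsFactors = FALSE)
  # include every node so none is dropped as isolated: give missing nodes a
  # non-edge row below threshold
  all_pairs <- pairs
  if (length(ids) >= 2) {
    miss <- setdiff(ids, unique(c(pairs$otu_i, pairs$otu_j)))
    for (nm in miss) {
      other <- setdiff(ids, nm)[1]
      all_pairs <- rbind(all_pairs,
                         data.frame(otu_i = nm, otu_j = other, rho = 0,
                                    p = 1, q = 1, stringsAsFactors = FALSE))
    }
  }
  build_network(all_pairs, rho_threshold = 0.7, q_threshold = 0.01)
}
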