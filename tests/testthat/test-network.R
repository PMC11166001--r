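test_that("the abundance/prevalence filter applies strict thresholds", {
  # 10 samples; OTU "edge" present in exactly 2 of 10 (prevalence 0.2, not > 0.2)
  m <- matrix(0L, 10, 4, dimnames = list(paste0("S", 1:10),
                                         c("common", "edge", "rare", "filler")))
  m[, "common"] <- 100L
  m[1:2, "edge"] <- 50L
  m[1, "rare"] <- 1L
  m[, "filler"] <- 10L
  tab <- otu_table(m)
  kept <- colnames(filter_otus(tab, min_mean_ra = 1e-4, min_prevalence = 0.20))
  expect_false("edge" %in% kept)     # 0.2 is not > 0.2
  expect_false("rare" %in% kept)
  expect_true(all(c("common", "filler") %in% kept))

  # 1% everywhere, present in all samples -> kept
  m2 <- matrix(c(99L, 1L), 10, 2, byrow = TRUE,
               dimnames = list(paste0("S", 1:10), c("big", "one_pct")))
  expect_true("one_pct" %in% colnames(filter_otus(otu_table(m2))))

  expect_error(filter_otus(tab, min_mean_ra = 0.9), "no OTU passes")
})

test_that("the filter reproduces a hand enumeration on a 10-OTU toy table", {
  set.seed(3)
  m <- random_counts(10, 10, lambda = 1)
  m[, 1] <- 200L                      # abundant and ubiquitous
  m[, 2] <- 0L; m[1:2, 2] <- 400L     # abundant but prevalence 0.2
  tab <- otu_table(m)
  ra <- sweep(m, 1, rowSums(m), "/")
  manual <- colnames(m)[colMeans(ra) > 1e-4 & colMeans(m > 0) > 0.2]
  expect_equal(colnames(filter_otus(tab)), manual)
})

test_that("Spearman correlation and BH adjustment match brute force", {
  # perfectly monotone pair
  m <- cbind(a = c(1L, 3L, 7L, 20L, 55L, 100L),
             b = c(2L, 4L, 9L, 30L, 60L, 150L),
             c = c(9L, 2L, 50L, 1L, 30L, 4L))
  rownames(m) <- paste0("S", 1:6)
  out <- correlate_otus(otu_table(m), use_relative = FALSE)
  expect_equal(out$rho[out$otu_i == "a" & out$otu_j == "b"], 1)

  set.seed(19)
  for (i in 1:15) {
    tab <- random_counts(sample(6:9, 1), 6, lambda = 6)
    out <- correlate_otus(otu_table(tab), use_relative = FALSE)
    man_rho <- apply(out, 1, function(r) {
      bf_spearman(tab[, r[["otu_i"]]], tab[, r[["otu_j"]]])
    })
    expect_equal(out$rho, unname(man_rho), tolerance = 1e-10)
    expect_equal(out$q, bf_bh(out$p), tolerance = 1e-12)
    # BH is order-preserving
    expect_true(all(diff(out$q[order(out$p)]) >= -1e-15))
  }

  # constant OTU excluded with a warning
  m2 <- cbind(m, k = c(5L, 5L, 5L, 5L, 5L, 5L))
  expect_warning(out2 <- correlate_otus(otu_table(m2), use_relative = FALSE),
                 "constant")
  expect_false("k" %in% c(out2$otu_i, out2$otu_j))

  expect_error(correlate_otus(otu_table(m[1:3, ])), ">= 4 samples")
})

test_that("edges require strictly exceeding both thresholds", {
  pairs <- data.frame(otu_i = c("A", "A", "B"), otu_j = c("B", "C", "C"),
                      rho = c(0.7, -0.9, 0.95), p = c(1e-4, 1e-5, 0.2),
                      q = c(0.001, 1e-4, 0.3), stringsAsFactors = FALSE)
  net <- build_network(pairs, rho_threshold = 0.7, q_threshold = 0.01)
  expect_equal(nrow(net$edges), 1)            # rho = 0.7 fails; q = 0.3 fails
  expect_equal(net$edges$sign, "negative")
  expect_equal(net$n_isolated, 1)             # B ends up isolated

  # monotone filtering: tightening thresholds never adds an edge
  set.seed(33)
  p <- data.frame(otu_i = paste0("X", 1:40), otu_j = paste0("Y", 1:40),
                  rho = runif(40, -1, 1), p = runif(40),
                  q = runif(40), stringsAsFactors = FALSE)
  e1 <- nrow(build_network(p, 0.5, 0.2)$edges)
  e2 <- nrow(build_network(p, 0.7, 0.2)$edges)
  e3 <- nrow(build_network(p, 0.7, 0.05)$edges)
  expect_gte(e1, e2)
  expect_gte(e2, e3)
})

test_that("topology matches closed forms on canonical graphs", {
  # complete graph K4
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  t4 <- network_topology(network_from_adj(k4))
  expect_equal(t4$avg_degree, 3)
  expect_equal(t4$avg_clustering, 1)
  expect_equal(t4$diameter, 1)
  expect_equal(t4$avg_path_length, 1)

  # path graph A-B-C
  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  t3 <- network_topology(network_from_adj(p3))
  expect_equal(t3$avg_clustering, 0)
  expect_equal(t3$diameter, 2)
  expect_equal(t3$avg_degree, 4 / 3)

  # two disjoint triangles: modularity of the clique partition is exactly 0.5
  tt <- matrix(0L, 6, 6)
  tt[1:3, 1:3] <- 1L; tt[4:6, 4:6] <- 1L; diag(tt) <- 0L
  net <- network_from_adj(tt)
  expect_equal(network_topology(net, seed = 1)$modularity, 0.5)
  expect_equal(bf_modularity(tt, c(1, 1, 1, 2, 2, 2)), 0.5)
})

test_that("topology and keystones equal brute force on random graphs", {
  set.seed(47)
  for (i in 1:60) {
    n <- sample(5:10, 1)
    adj <- random_graph_adj(n, p = runif(1, 0.25, 0.6))
    if (sum(adj) == 0) next
    net <- network_from_adj(adj)
    keep <- match(net$nodes$otu, paste0("O", seq_len(n)))
    sub <- adj[keep, keep, drop = FALSE]

    topo <- network_topology(net, seed = 1)
    expect_equal(topo$avg_degree, sum(sub) / nrow(sub))
    expect_equal(topo$avg_clustering, mean(bf_local_clustering(sub)),
                 tolerance = 1e-12)
    d <- bf_distances(sub)
    in_lcc <- which(rowSums(is.finite(d)) == max(rowSums(is.finite(d))))
    # largest component = nodes reaching the most others
    lcc <- which(is.finite(d[in_lcc[1], ]))
    dl <- d[lcc, lcc]
    expect_equal(topo$diameter, max(dl))
    expect_equal(topo$avg_path_length, mean(dl[upper.tri(dl)]), tolerance = 1e-12)

    if (nrow(sub) >= 5) {
      ks <- keystone_taxa(net)
      deg <- rowSums(sub)
      btw <- bf_betweenness(sub, normalized = TRUE)
      dc <- quantile(deg, 0.8, names = FALSE)
      hi <- deg >= dc
      bc <- quantile(btw[hi], 0.2, names = FALSE)
      manual <- net$nodes$otu[hi & btw <= bc * (1 + 1e-9) + 1e-12]
      expect_setequal(ks$keystones, manual)
      # invariants: keystones within the high-degree set, low betweenness
      expect_true(all(ks$keystones %in% net$nodes$otu[hi]))
    }
  }
})

test_that("keystone logic on symmetric and star graphs", {
  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  ks <- keystone_taxa(network_from_adj(k6))
  expect_setequal(ks$keystones, paste0("O", 1:6))   # total symmetry: ties kept

  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- 1L; star[2:6, 1] <- 1L
  ks2 <- keystone_taxa(network_from_adj(star))
  expect_false("O1" %in% ks2$keystones)   # hub: top degree but maximal betweenness

  expect_error(keystone_taxa(network_from_adj(k6), degree_quantile = 1.2),
               "quantiles")
})

test_that("split networks are computed independently per stratum", {
  set.seed(71)
  half <- random_counts(8, 30, lambda = 4)
  m <- rbind(half, half)
  rownames(m) <- paste0("S", 1:16)
  tab <- otu_table(m)
  meta <- sample_frame(data.frame(
    sample_id = rownames(m),
    season = rep(c("summer", "winter"), each = 8),
    lifestyle = "FL"))
  sn <- split_networks(tab, meta, split_cols = "season",
                       min_mean_ra = 0, min_prevalence = 0.1,
                       rho_threshold = 0.6, q_threshold = 0.5)
  # identical halves give identical topology
  expect_equal(sn$topology$edges[1], sn$topology$edges[2])
  expect_equal(sn$topology$avg_degree[1], sn$topology$avg_degree[2])

  meta_bad <- sample_frame(data.frame(
    sample_id = rownames(m),
    season = c(rep("summer", 3), rep("winter", 13)),
    lifestyle = "FL"))
  expect_error(split_networks(tab, meta_bad, split_cols = "season"),
               "fewer than 4")
})
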