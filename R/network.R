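#' Abundance/prevalence filter before network inference
#'
#' Keeps an OTU only if its mean relative abundance across samples strictly
#' exceeds `min_mean_ra` (default 0.01%) and it is present in strictly more
#' than `min_prevalence` of the samples (default 20%). The mean-abundance
#' reading of the filter is the standard convention in microbial network
#' studies; a per-sample reading (abundance above the cutoff in every sample)
#' is available via `per_sample = TRUE`.
#'
#' @param table an [otu_table()].
#' @param min_mean_ra mean relative-abundance cutoff (strict, proportion).
#' @param min_prevalence prevalence cutoff (strict, fraction of samples).
#' @param per_sample require the abundance cutoff in every sample instead of
#'   on the mean.
#' @return the filtered [otu_table()].
#' @export
filter_otus <- function(table, min_mean_ra = 1e-4, min_prevalence = 0.20,
                        per_sample = FALSE) {
  stopifnot(is_otu_table(table))
  ra <- relative_abundance(table)
  abun_ok <- if (per_sample) {
    apply(ra, 2, function(x) all(x > min_mean_ra))
  } else {
    colMeans(ra) > min_mean_ra
  }
  prev_ok <- colMeans(unclass(table) > 0) > min_prevalence
  keep <- abun_ok & prev_ok
  if (!any(keep)) stop("no OTU passes the abundance/prevalence filter", call. = FALSE)
  table[, keep, drop = FALSE]
}

#' All-pairs Spearman correlations with BH adjustment
#'
#' Rank correlation (average ranks on ties) between every OTU pair across
#' samples, computed on relative abundances; the two-sided p-value uses the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))`, and Benjamini-Hochberg
#' adjustment is applied once over all tested pairs jointly. Pairs involving
#' a constant OTU have undefined rho; they are dropped and counted in the
#' `"n_constant"` attribute.
#'
#' @param table an [otu_table()] with >= 4 samples (filtered via
#'   [filter_otus()] in the standard chain).
#' @param use_relative correlate relative abundances (default) or raw counts.
#' @return data.frame with columns `otu_i`, `otu_j`, `rho`, `p`, `q`;
#'   attribute `"n_samples"`.
#' @export
correlate_otus <- function(table, use_relative = TRUE) {
  stopifnot(is.matrix(table))
  n <- nrow(table)
  if (n < 4) stop("need >= 4 samples for correlation p-values", call. = FALSE)
  m <- if (use_relative) relative_abundance(table) else {
    x <- unclass(table); storage.mode(x) <- "double"; x
  }
  constant <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant OTU(s) excluded from correlation", call. = FALSE)
  }
  keep <- colnames(m)[!constant]
  if (length(keep) < 2) stop("fewer than 2 variable OTUs", call. = FALSE)
  rho <- stats::cor(m[, keep, drop = FALSE], method = "spearman")
  up <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[up]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  out <- data.frame(otu_i = keep[up[, 1]], otu_j = keep[up[, 2]],
                    rho = r, p = p, q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  attr(out, "n_constant") <- sum(constant)
  out
}

#' Build a co-occurrence network from correlation results
#'
#' An edge joins two OTUs when `|rho|` strictly exceeds `rho_threshold` and
#' the BH-adjusted p-value is strictly below `q_threshold` (the conventional
#' 0.7 / 0.01 pair by default). OTUs left without any edge are dropped from
#' the graph and counted. Edge sign records whether the correlation is
#' positive or negative; topology is computed on the unsigned graph.
#'
#' @param pairs output of [correlate_otus()].
#' @param rho_threshold absolute-correlation cutoff (strict).
#' @param q_threshold adjusted-p cutoff (strict).
#' @param table optional [otu_table()] used to annotate nodes with mean
#'   relative abundance and prevalence.
#' @param taxonomy optional named character vector of taxonomy strings.
#' @return object of class `cooc_network`: list with `graph` (igraph),
#'   `nodes`, `edges` data.frames, `n_isolated`, and the thresholds.
#' @export
build_network <- function(pairs, rho_threshold = 0.7, q_threshold = 0.01,
                          table = NULL, taxonomy = NULL) {
  stopifnot(is.data.frame(pairs), all(c("otu_i", "otu_j", "rho", "q") %in% names(pairs)))
  sel <- abs(pairs$rho) > rho_threshold & pairs$q < q_threshold
  edges <- pairs[sel, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  all_otus <- unique(c(pairs$otu_i, pairs$otu_j))
  used <- unique(c(edges$otu_i, edges$otu_j))
  nodes <- data.frame(otu = used, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    ra <- relative_abundance(table)
    nodes$mean_ra <- colMeans(ra)[nodes$otu]
    nodes$prevalence <- colMeans(unclass(table) > 0)[nodes$otu]
  }
  nodes$taxonomy <- if (!is.null(taxonomy)) unname(taxonomy[nodes$otu]) else
    rep(NA_character_, nrow(nodes))
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_i", "otu_j", "rho", "q", "sign")],
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes,
                 edges = edges[, c("otu_i", "otu_j", "rho", "p", "q", "sign")],
                 n_isolated = length(all_otus) - length(used),
                 rho_threshold = rho_threshold, q_threshold = q_threshold),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (|rho| > %g, q < %g), %d isolated OTU(s) dropped\n",
              nrow(x$nodes), nrow(x$edges), x$rho_threshold, x$q_threshold,
              x$n_isolated))
  invisible(x)
}

#' Network-level topology summary
#'
#' Metrics on the unweighted, undirected graph: node and edge counts,
#' proportion of positive edges, average degree (`2E/N`), average local
#' clustering coefficient (nodes of degree < 2 contribute 0), average
#' shortest-path length and diameter on the largest connected component, and
#' modularity of a seeded Louvain partition. Path metrics of an empty graph
#' are `NA`.
#'
#' @param net a `cooc_network`.
#' @param seed seed for the Louvain partition (its only stochastic step).
#' @return one-row data.frame.
#' @export
network_topology <- function(net, seed = 1L) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0 || e == 0) {
    return(data.frame(nodes = n, edges = e, prop_positive = NA_real_,
                      avg_degree = if (n > 0) 2 * e / n else NA_real_,
                      avg_clustering = NA_real_, avg_path_length = NA_real_,
                      diameter = NA_real_, modularity = NA_real_,
                      n_components = if (n > 0) igraph::count_components(g) else 0L))
  }
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  community <- with_seed_or_now(seed, igraph::cluster_louvain(g))
  data.frame(nodes = n, edges = e,
             prop_positive = mean(igraph::E(g)$sign == "positive"),
             avg_degree = 2 * e / n,
             avg_clustering = mean(loc),
             avg_path_length = igraph::mean_distance(sub, directed = FALSE),
             diameter = igraph::diameter(sub, directed = FALSE, weights = NA),
             modularity = igraph::modularity(community),
             n_components = comp$no)
}

#' Keystone OTU detection
#'
#' Keystones are the classic high-degree / low-betweenness nodes: members of
#' the high-degree set H (degree at or above the `degree_quantile` empirical
#' quantile of all node degrees, ties kept) whose normalised shortest-path
#' betweenness is at or below the `betweenness_quantile` quantile within H.
#' The realised cutoffs are data-dependent and returned alongside the set.
#'
#' @param net a `cooc_network` with >= 5 nodes.
#' @param degree_quantile upper-tail degree quantile (default 0.80 = top 20%).
#' @param betweenness_quantile lower-tail betweenness quantile within the
#'   high-degree set (default 0.20 = bottom 20%).
#' @return list with `keystones` (character vector), `degree_cutoff`,
#'   `betweenness_cutoff`, and `table` (per-node degree, betweenness,
#'   high-degree and keystone flags).
#' @export
keystone_taxa <- function(net, degree_quantile = 0.80,
                          betweenness_quantile = 0.20) {
  stopifnot(inherits(net, "cooc_network"))
  if (degree_quantile <= 0 || degree_quantile >= 1 ||
      betweenness_quantile <= 0 || betweenness_quantile >= 1) {
    stop("quantiles must lie in (0, 1)", call. = FALSE)
  }
  g <- net$graph
  if (igraph::vcount(g) < 5) stop("need >= 5 nodes for keystone detection", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  deg_cut <- stats::quantile(deg, degree_quantile, names = FALSE)
  high <- deg >= deg_cut
  btw_cut <- stats::quantile(btw[high], betweenness_quantile, names = FALSE)
  # inclusive at the cutoff: ties are kept, with a small numerical tolerance
  # (betweenness values are accumulated sums of path fractions)
  key <- high & btw <= btw_cut * (1 + 1e-9) + 1e-12
  tab <- data.frame(otu = names(deg), degree = as.integer(deg),
                    betweenness = unname(btw), high_degree = unname(high),
                    keystone = unname(key), row.names = NULL,
                    stringsAsFactors = FALSE)
  list(keystones = tab$otu[tab$keystone], degree_cutoff = deg_cut,
       betweenness_cutoff = btw_cut, table = tab)
}

#' Per-stratum co-occurrence networks
#'
#' Runs the full filter -> correlate -> build chain independently within each
#' stratum of the sample metadata (e.g. season x lifestyle, or nearshore vs
#' offshore site sets) and emits a comparative topology table.
#'
#' @param table an [otu_table()].
#' @param meta a `sample_frame` covering the table's samples.
#' @param split_cols metadata column names whose interaction defines the
#'   strata; every stratum needs >= 4 samples.
#' @param taxonomy optional named taxonomy vector for node annotation.
#' @param seed seed for the Louvain step of each topology summary.
#' @param ... passed to [filter_otus()] and [build_network()]
#'   (`min_mean_ra`, `min_prevalence`, `rho_threshold`, `q_threshold`).
#' @return list with `networks` (named list of `cooc_network`) and `topology`
#'   (one row per stratum).
#' @export
split_networks <- function(table, meta, split_cols = c("season", "lifestyle"),
                           taxonomy = NULL, seed = 1L, ...) {
  stopifnot(is_otu_table(table), inherits(meta, "sample_frame"))
  missing_cols <- setdiff(split_cols, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks split column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
  strata <- interaction(meta[split_cols], sep = "_", drop = TRUE)
  dots <- list(...)
  filt_args <- dots[names(dots) %in% c("min_mean_ra", "min_prevalence", "per_sample")]
  net_args <- dots[names(dots) %in% c("rho_threshold", "q_threshold")]
  nets <- list()
  topo <- list()
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    if (length(idx) < 4) {
      stop("stratum '", lv, "' has fewer than 4 samples", call. = FALSE)
    }
    sub <- table[idx, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    filt <- do.call(filter_otus, c(list(sub), filt_args))
    pairs <- correlate_otus(filt)
    net <- do.call(build_network,
                   c(list(pairs, table = filt, taxonomy = taxonomy), net_args))
    nets[[lv]] <- net
    topo[[lv]] <- cbind(data.frame(stratum = lv, n_samples = length(idx)),
                        network_topology(net, seed = seed))
  }
  list(networks = nets, topology = do.call(rbind, topo))
}
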