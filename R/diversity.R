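#' Rarefy an OTU table to even depth
#'
#' Subsamples every sample, without replacement, to the same number of reads
#' — by default the minimum library size, the convention for putting uneven
#' amplicon libraries on a common footing before diversity and null-model
#' work. Samples whose total is below an explicit `depth` are dropped with a
#' warning rather than erroring, mirroring standard practice.
#'
#' @param table an [otu_table()].
#' @param depth integer target depth, or `"min"` for the smallest library.
#' @param seed integer seed (subsampling is random) or `NULL` to use the
#'   current RNG state.
#' @return an [otu_table()] in which every sample totals exactly `depth`.
#' @export
rarefy_table <- function(table, depth = "min", seed = NULL) {
  stopifnot(is_otu_table(table))
  totals <- rowSums(table)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("depth must be a positive integer", call. = FALSE)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  if (any(drop)) {
    warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(table)[drop], collapse = ", "), call. = FALSE)
    table <- table[!drop, , drop = FALSE]
  }
  # rrarefy's advisory warning (fires whenever a table has no singletons) is
  # noise here; depth and count validation happen above
  out <- with_seed_or_now(seed,
                          suppressWarnings(vegan::rrarefy(unclass(table), depth)))
  otu_table(out)
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` over the positive proportions of one count vector,
#' in nats by default (the Mothur convention; typical marine communities run
#' around 4-6 nats). Give `base = 2` for bits.
#'
#' @param counts non-negative count vector with a positive total, or an
#'   [otu_table()] for per-sample values.
#' @param base logarithm base.
#' @return numeric scalar (vector input) or named vector (table input).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) {
    return(apply(unclass(counts), 1, shannon, base = base))
  }
  check_count_vector(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Chao1 richness estimate
#'
#' Bias-corrected by default: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`
#' singletons and `F2` doubletons, which stays defined when there are no
#' doubletons. The classic estimator `S_obs + F1^2 / (2 F2)` is available via
#' `bias_corrected = FALSE` (undefined when `F2 = 0` unless `F1 = 0`).
#'
#' @param counts integer count vector, or an [otu_table()].
#' @param bias_corrected logical.
#' @return numeric scalar or named per-sample vector; always `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (is.matrix(counts)) {
    return(apply(unclass(counts), 1, chao1, bias_corrected = bias_corrected))
  }
  check_count_vector(counts, integer_only = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) {
      if (f1 == 0) return(s_obs)
      return(NaN)
    }
    s_obs + f1^2 / (2 * f2)
  }
}

#' Good's coverage
#'
#' `1 - F1 / N`: the estimated fraction of the community represented by a
#' sample of `N` reads with `F1` singleton OTUs.
#'
#' @param counts integer count vector with positive total, or an
#'   [otu_table()].
#' @return numeric in `[0, 1]`, scalar or per-sample vector.
#' @export
goods_coverage <- function(counts) {
  if (is.matrix(counts)) return(apply(unclass(counts), 1, goods_coverage))
  check_count_vector(counts, integer_only = TRUE)
  1 - sum(counts == 1) / sum(counts)
}

check_count_vector <- function(counts, integer_only = FALSE) {
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and free of NA", call. = FALSE)
  }
  if (integer_only && any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("count vector has zero total", call. = FALSE)
  invisible(counts)
}

#' Per-sample alpha-diversity table
#'
#' @param table an [otu_table()].
#' @param base logarithm base for Shannon.
#' @return data.frame: `sample_id`, `depth`, `s_obs`, `shannon`, `chao1`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(is_otu_table(table))
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             depth = as.integer(rowSums(m)),
             s_obs = as.integer(rowSums(m > 0)),
             shannon = shannon(table, base = base),
             chao1 = chao1(table),
             goods_coverage = goods_coverage(table),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, via [vegan::vegdist()].
#'
#' @param table an [otu_table()] (or abundance matrix, samples x OTUs) with
#'   at least 2 samples.
#' @return a `dist` with sample labels; entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(m) <= 0)) stop("sample with zero total", call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. `R = (mean between-group rank - mean
#' within-group rank) / (M / 2)` with `M = n(n-1)/2`; the p-value uses the
#' add-one convention `p = (1 + #{perm R >= obs R}) / (1 + n_perm)` so it is
#' never zero.
#'
#' @param dm a `dist` or square symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed or `NULL`.
#' @return list with `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(dm)
  n <- nrow(d)
  groups <- as.factor(groups)
  stopifnot(length(groups) == n)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 members", call. = FALSE)
  up <- upper.tri(d)
  rk <- rank(d[up])
  M <- n * (n - 1) / 2
  stat_for <- function(g) {
    within <- outer(g, g, "==")[up]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- stat_for(groups)
  with_seed_or_now(seed, {
    hits <- sum(vapply(seq_len(n_perm),
                       function(i) stat_for(sample(groups)) >= obs,
                       logical(1)))
    list(statistic = obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm)
  })
}
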