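#' Mantel test between two distance matrices
#'
#' Pearson correlation between the upper-triangle entries of two distance
#' matrices over the same samples, tested by simultaneous row/column
#' permutation of the second matrix. One-sided by default (positive
#' association, the usual ecological question: do community and environmental
#' distances increase together?), with the add-one convention
#' `p = (1 + #{perm r >= obs r}) / (1 + n_perm)` so p is never zero.
#'
#' @param dm_a,dm_b `dist` objects or square symmetric matrices with the same
#'   samples in the same order (>= 4 samples).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed or `NULL`.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return list with `r`, `p_value`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(dm_a)
  b <- as.matrix(dm_b)
  if (!identical(dim(a), dim(b))) stop("distance matrices differ in size", call. = FALSE)
  n <- nrow(a)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb)) {
    if (!identical(la, lb)) {
      if (setequal(la, lb)) {
        b <- b[la, la]
      } else {
        stop("distance matrices are over different samples", call. = FALSE)
      }
    }
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  up <- upper.tri(a)
  va <- a[up]
  obs <- stats::cor(va, b[up])
  score <- function(r) if (alternative == "greater") r else abs(r)
  with_seed_or_now(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      r <- stats::cor(va, b[pm, pm][up])
      if (score(r) >= score(obs)) hits <- hits + 1L
    }
    list(r = obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm,
         alternative = alternative)
  })
}

#' Environmental distance between samples
#'
#' Each requested variable is standardised to zero mean and unit variance
#' (units are incommensurate: degrees C, PSU, umol/L, ...) before Euclidean
#' distance. With one variable this reduces to `|x_i - x_j| / sd(x)`. Missing
#' values propagate via pairwise-complete coordinates (with a warning), the
#' [stats::dist()] convention of rescaling by the number of available
#' coordinates.
#'
#' @param meta a `sample_frame` (see [read_metadata()]).
#' @param variables character vector of numeric metadata columns (>= 1).
#' @return a `dist` labelled by sample id.
#' @export
env_distance <- function(meta, variables) {
  stopifnot(inherits(meta, "sample_frame"), length(variables) >= 1)
  missing_cols <- setdiff(variables, names(meta))
  if (length(missing_cols)) {
    stop("unknown metadata variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(meta[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("environmental variables must be numeric", call. = FALSE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- variables[is.na(sds) | sds == 0]
  if (length(zero)) {
    stop("zero-variance variable(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x)) {
    warning("missing environmental values: pairwise-complete distances", call. = FALSE)
  }
  z <- scale(x)
  rownames(z) <- meta$sample_id
  stats::dist(z)
}

#' Spearman correlations between an abundance vector and environmental variables
#'
#' One row per variable: Spearman rho and two-sided p (pairwise-complete on
#' missing values), plus BH-adjusted q across the variable family. Variables
#' with fewer than 4 complete pairs are reported with `NA` statistics.
#'
#' @param abundance named numeric vector (names = sample ids), e.g. 16S gene
#'   copies or an OTU's abundance per sample.
#' @param meta a `sample_frame` containing those samples.
#' @param variables numeric metadata columns to test; defaults to the
#'   `env_vars` attribute of `meta`.
#' @return data.frame with columns `variable`, `n`, `rho`, `p`, `q`.
#' @export
env_abundance_correlations <- function(abundance, meta,
                                       variables = attr(meta, "env_vars")) {
  stopifnot(inherits(meta, "sample_frame"), length(variables) >= 1)
  if (is.null(names(abundance))) stop("abundance vector must be named by sample id", call. = FALSE)
  idx <- match(meta$sample_id, names(abundance))
  if (all(is.na(idx))) stop("no abundance entries match metadata sample ids", call. = FALSE)
  ab <- abundance[idx]
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    ok <- !is.na(x) & !is.na(ab)
    if (sum(ok) < 4) {
      return(data.frame(variable = v, n = sum(ok), rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(ab[ok], x[ok], method = "spearman", exact = FALSE))
    data.frame(variable = v, n = sum(ok), rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Group-difference tests (thin delegations)
#'
#' Convenience wrapper over the standard two-group routines the diversity and
#' abundance comparisons use: Mann-Whitney U (independent groups), Wilcoxon
#' signed rank (paired), or the independent-samples t-test. These are routine
#' statistics delegated to [stats::wilcox.test()] / [stats::t.test()], not
#' re-implementations.
#'
#' @param values numeric vector of observations.
#' @param groups two-level factor (same length as `values`). For the paired
#'   signed-rank test the two groups are paired by order within group.
#' @param test one of `"mann_whitney"`, `"wilcoxon_signed_rank"`,
#'   `"t_independent"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
group_difference <- function(values, groups,
                             test = c("mann_whitney", "wilcoxon_signed_rank",
                                      "t_independent")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) != 2) stop("need exactly 2 groups", call. = FALSE)
  lv <- levels(droplevels(groups))
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  ht <- switch(test,
    mann_whitney = suppressWarnings(stats::wilcox.test(x, y)),
    wilcoxon_signed_rank = {
      if (length(x) != length(y)) stop("paired test needs equal group sizes", call. = FALSE)
      if (all(x == y)) stop("all paired differences are zero: signed-rank test undefined",
                            call. = FALSE)
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    },
    t_independent = stats::t.test(x, y))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}
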