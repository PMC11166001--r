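#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For a sample pair (A, B), the average patristic distance from each OTU in
#' A to its nearest relative in B and vice versa:
#' `0.5 * (sum_i w_iA min_j d(i,j) + sum_j w_jB min_i d(j,i))`. Weights are
#' relative abundances when `weighted = TRUE` (the Stegen-framework default)
#' or `1/richness` otherwise; only OTUs with positive count in the respective
#' sample participate. An OTU shared by both samples contributes distance 0,
#' so identical communities score 0.
#'
#' @param table an [otu_table()] whose OTU ids are tips of `tree`.
#' @param tree a `phylo` with branch lengths.
#' @param weighted abundance-weighted (default) or presence-based weights.
#' @return symmetric sample-by-sample matrix in branch-length units.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  prep <- assembly_prep(table, tree, weighted)
  out <- bmntd_cpp(prep$D, prep$W, prep$tip)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

assembly_prep <- function(table, tree, weighted) {
  stopifnot(is.matrix(table))
  validate_phylogeny(tree)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing)) {
    stop("OTU(s) absent from tree: ", paste(utils::head(missing, 3), collapse = ", "),
         " (run align_data first)", call. = FALSE)
  }
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (any(rowSums(m) <= 0)) stop("sample with zero total", call. = FALSE)
  W <- if (weighted) {
    sweep(m, 1, rowSums(m), "/")
  } else {
    pres <- (m > 0) * 1
    sweep(pres, 1, rowSums(pres), "/")
  }
  D <- patristic(tree)
  tip <- match(colnames(table), tree$tip.label)
  list(D = D, W = W, tip = tip)
}

#' Beta nearest taxon index (betaNTI)
#'
#' The z-score of observed betaMNTD against a null distribution obtained by
#' shuffling tip labels across the whole phylogeny (equivalently, permuting
#' the rows/columns of the patristic matrix) while holding the table fixed.
#' `|betaNTI| > 2` flags deterministic selection: above +2 heterogeneous,
#' below -2 homogeneous. Pairs whose null distribution has zero spread (e.g.
#' on a star phylogeny, where every shuffle leaves betaMNTD unchanged) are
#' reported as `NA` with `undefined = TRUE` and a warning, and must be
#' excluded from classification.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (>= 99; 999 is conventional).
#' @param seed integer seed or `NULL`.
#' @return object of class `bnti_result`: list with matrices `bnti`,
#'   `bmntd_obs`, `null_mean`, `null_sd`, and logical `undefined`.
#' @export
beta_nti <- function(table, tree, n_null = 999, weighted = TRUE, seed = NULL) {
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  prep <- assembly_prep(table, tree, weighted)
  n_tip <- nrow(prep$D)
  res <- with_seed_or_now(seed, {
    perms <- matrix(0L, n_null, n_tip)
    for (r in seq_len(n_null)) perms[r, ] <- sample.int(n_tip)
    bmntd_null_cpp(prep$D, prep$W, prep$tip, perms)
  })
  ids <- rownames(table)
  # a pair is degenerate when the null distribution has (numerically) no
  # spread: the tip shuffle leaves betaMNTD unchanged
  undef <- (res$null_max - res$null_min) <= 1e-10 * pmax(abs(res$null_max), 1)
  diag(undef) <- FALSE
  bnti <- (res$obs - res$null_mean) / res$null_sd
  bnti[undef] <- NA_real_
  diag(bnti) <- NA_real_
  if (any(undef)) {
    warning(sum(undef[upper.tri(undef)]),
            " pair(s) with degenerate null (sd = 0); betaNTI undefined there",
            call. = FALSE)
  }
  dimnames(bnti) <- dimnames(undef) <- dimnames(res$obs) <-
    dimnames(res$null_mean) <- dimnames(res$null_sd) <- list(ids, ids)
  structure(list(bnti = bnti, bmntd_obs = res$obs, null_mean = res$null_mean,
                 null_sd = res$null_sd, undefined = undef,
                 n_null = n_null, weighted = weighted),
            class = "bnti_result")
}

#' Bray-Curtis-based Raup-Crick metric (RCbray)
#'
#' Position of the observed Bray-Curtis dissimilarity of a sample pair within
#' a probabilistic assembly null, rescaled to `[-1, 1]`. Null communities
#' preserve each sample's observed richness and total count; species enter a
#' null community with probability proportional to their occurrence frequency
#' across the supplied samples, and individuals are then assigned with
#' probability proportional to metacommunity relative abundance.
#' `RC = 2 ((#null < obs) + 0.5 (#null = obs)) / n_null - 1`, so values near
#' +1 mean the pair is more dissimilar than expected by chance (dispersal
#' limitation) and values near -1 less dissimilar (homogenizing dispersal).
#'
#' @param table an [otu_table()] (integer counts). The samples given define
#'   the metacommunity; OTUs absent from all of them are ignored.
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed or `NULL`.
#' @return symmetric matrix of RC values in `[-1, 1]` (`NA` diagonal).
#' @export
rc_bray <- function(table, n_null = 999, seed = NULL) {
  stopifnot(is_otu_table(table))
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  m <- unclass(table)
  m <- m[, colSums(m) > 0, drop = FALSE]
  out <- with_seed_or_now(seed, rc_bray_cpp(m, as.integer(n_null)))
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Classify a sample pair into one of five assembly processes
#'
#' The two-tier rule: `betaNTI > 2` means heterogeneous selection and
#' `betaNTI < -2` homogeneous selection; otherwise the stochastic class is
#' read off RCbray (`> 0.95` dispersal limitation, `< -0.95` homogenizing
#' dispersal, else ecological drift). All inequalities are strict, so values
#' landing exactly on a threshold fall to the stochastic side (betaNTI) or to
#' drift (RC).
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RCbray values (recycled pairwise with `bnti`).
#' @return factor with levels heterogeneous_selection, homogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal, drift.
#' @export
classify_pair <- function(bnti, rc) {
  if (anyNA(bnti) || anyNA(rc)) {
    stop("classify_pair requires defined betaNTI and RCbray values", call. = FALSE)
  }
  if (any(rc < -1 | rc > 1)) stop("RCbray outside [-1, 1]", call. = FALSE)
  out <- ifelse(bnti > 2, "heterogeneous_selection",
         ifelse(bnti < -2, "homogeneous_selection",
         ifelse(rc > 0.95, "dispersal_limitation",
         ifelse(rc < -0.95, "homogenizing_dispersal", "drift"))))
  factor(out, levels = process_levels)
}

#' Null-model partition of community assembly processes
#'
#' Runs betaNTI and RCbray over all sample pairs within each stratum
#' (by default season x lifestyle) and classifies every pair with
#' [classify_pair()], returning per-pair metrics and per-stratum fractions of
#' the five processes. Each stratum is treated as its own metacommunity for
#' the Raup-Crick null, and the tip shuffle runs across the whole supplied
#' phylogeny. Pairs with a degenerate betaNTI null are excluded from the
#' fractions and counted.
#'
#' @param table an [otu_table()], OTUs aligned with `tree`.
#' @param tree a `phylo`.
#' @param groups stratum label per sample (character/factor, recycled against
#'   `rownames(table)`); every stratum needs >= 2 samples.
#' @param n_null null replicates for both metrics.
#' @param weighted abundance-weighted betaMNTD.
#' @param seed integer seed; per-stratum streams are derived from it.
#' @return object of class `assembly_partition`: list with `pairs` (one row
#'   per within-stratum pair: stratum, sample ids, bmntd, bnti, rc, process)
#'   and `fractions` (one row per stratum: the five process fractions, which
#'   sum to 1 over defined pairs, plus `n_pairs` and `n_undefined`).
#' @export
assembly_partition <- function(table, tree, groups, n_null = 999,
                               weighted = TRUE, seed = NULL) {
  stopifnot(is_otu_table(table))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(table))
  strata <- split(seq_len(nrow(table)), groups)
  small <- names(strata)[vapply(strata, length, integer(1)) < 2]
  if (length(small)) {
    stop("stratum with < 2 samples: ", paste(small, collapse = ", "), call. = FALSE)
  }
  pair_rows <- list()
  frac_rows <- list()
  for (g in seq_along(strata)) {
    idx <- strata[[g]]
    sub <- table[idx, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    sseed <- if (is.null(seed)) NULL else as.integer(seed) + g
    nti <- suppressWarnings(
      beta_nti(sub, tree, n_null = n_null, weighted = weighted, seed = sseed))
    rc <- rc_bray(sub, n_null = n_null,
                  seed = if (is.null(sseed)) NULL else sseed + 7919L)
    up <- which(upper.tri(nti$bnti), arr.ind = TRUE)
    df <- data.frame(stratum = names(strata)[g],
                     sample_i = rownames(sub)[up[, 1]],
                     sample_j = rownames(sub)[up[, 2]],
                     bmntd = nti$bmntd_obs[up],
                     bnti = nti$bnti[up],
                     rc = rc[up],
                     stringsAsFactors = FALSE)
    ok <- !is.na(df$bnti)
    df$process <- NA_character_
    if (any(ok)) {
      df$process[ok] <- as.character(classify_pair(df$bnti[ok], df$rc[ok]))
    }
    pair_rows[[g]] <- df
    counts <- table(factor(df$process[ok], levels = process_levels))
    fr <- as.numeric(counts) / max(sum(ok), 1L)
    frac_rows[[g]] <- data.frame(stratum = names(strata)[g],
                                 as.list(stats::setNames(fr, process_levels)),
                                 n_pairs = sum(ok), n_undefined = sum(!ok),
                                 stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, pair_rows),
                 fractions = do.call(rbind, frac_rows),
                 n_null = n_null, weighted = weighted),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("assembly_partition over", nrow(x$fractions), "stratum/strata,",
      nrow(x$pairs), "sample pairs (n_null =", x$n_null, ")\n")
  print(x$fractions, row.names = FALSE)
  invisible(x)
}
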