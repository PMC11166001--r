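#' Configuration for the synthetic community generator
#'
#' The generator emulates the structure of a seasonal, two-lifestyle marine
#' amplicon survey: a season x lifestyle x site x depth design (default 52
#' summer samples, 26 free-living + 26 particle-associated over 6 sites, and
#' 68 winter samples, 34 + 34 over 7 sites), thousands of OTUs, uneven
#' log-normal library sizes, phylogenetically conserved environmental optima
#' (Brownian trait on a pure-birth tree), Gaussian environmental filtering on
#' one latent gradient, a tunable dispersal regime, and optional planted
#' correlation blocks that give the network stage a known answer.
#'
#' @param n_otus number of OTUs (tree tips).
#' @param groups data.frame with columns `season`, `lifestyle`, `n_sites`,
#'   `n` giving the number of samples per design cell; the default mirrors a
#'   120-sample two-season survey.
#' @param library_meanlog,library_sdlog log-normal parameters of library
#'   size; defaults give uneven depths around 4e4 reads (minimum in the
#'   high 2e4s), matching deep modern amplicon runs.
#' @param tree_depth expected depth of the pure-birth tree (time units; the
#'   birth rate is chosen so tips appear at roughly this depth).
#' @param trait_signal phylogenetic-signal strength of the environmental
#'   optima: optima = `trait_signal` * standardised Brownian trait + i.i.d.
#'   standard normal noise. 0 means no signal.
#' @param sigma_sel niche breadth of the Gaussian environmental filter, in
#'   gradient units. `Inf` switches selection off (neutral).
#' @param dispersal `"well_mixed"` (one metacommunity pool) or `"limited"`
#'   (`k_pools` source pools with independently permuted metacommunity
#'   weights; samples cycle across pools).
#' @param k_pools number of source pools when `dispersal = "limited"`.
#' @param blocks list of `list(size =, rho =)` planted-correlation blocks
#'   (disjoint OTU sets rebuilt from a shared latent log-normal factor).
#' @param env_range half-width of the environmental gradient (gradient
#'   units; optima have total sd about `sqrt(1 + trait_signal^2)`).
#' @param env_mode how samples sit on the gradient: `"uniform"` draws each
#'   sample's environment independently from
#'   `U(-env_range, env_range)`; `"site_gradient"` places the sites of each
#'   design cell at evenly spaced positions spanning the gradient (the
#'   transect structure of a nearshore-offshore section) with a small
#'   within-site jitter (5% of `env_range`).
#' @param seed integer seed; every generator is fully deterministic under it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_otus = 2000,
                         groups = data.frame(
                           season = c("summer", "summer", "winter", "winter"),
                           lifestyle = c("FL", "PA", "FL", "PA"),
                           n_sites = c(6, 6, 7, 7),
                           n = c(26, 26, 34, 34)),
                         library_meanlog = log(4e4), library_sdlog = 0.15,
                         tree_depth = 1,
                         trait_signal = 1,
                         sigma_sel = 1,
                         dispersal = c("well_mixed", "limited"),
                         k_pools = 4,
                         blocks = list(),
                         env_range = 2,
                         env_mode = c("uniform", "site_gradient"),
                         seed = 1L) {
  dispersal <- match.arg(dispersal)
  env_mode <- match.arg(env_mode)
  stopifnot(n_otus >= 2, all(groups$n >= 1), library_sdlog >= 0,
            tree_depth > 0, trait_signal >= 0, sigma_sel > 0,
            k_pools >= 1, env_range > 0)
  for (b in blocks) {
    stopifnot(b$size >= 2, b$rho > -1, b$rho < 1)
  }
  if (sum(vapply(blocks, `[[`, numeric(1), "size")) > n_otus) {
    stop("correlation blocks exceed the number of OTUs", call. = FALSE)
  }
  structure(list(n_otus = as.integer(n_otus), groups = groups,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 tree_depth = tree_depth, trait_signal = trait_signal,
                 sigma_sel = sigma_sel, dispersal = dispersal,
                 k_pools = as.integer(k_pools), blocks = blocks,
                 env_range = env_range, env_mode = env_mode,
                 seed = as.integer(seed)),
            class = "synth_config")
}

with_seed_or_now <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate a pure-birth phylogeny over OTUs
#'
#' @param n_otus number of tips (>= 2).
#' @param depth approximate expected tree depth (branch-length units).
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return a `phylo` with tips `OTU0001 ...`, all branch lengths > 0.
#' @export
simulate_tree <- function(n_otus, depth = 1, seed = NULL) {
  stopifnot(n_otus >= 2, depth > 0)
  with_seed_or_now(seed, {
    # pure birth; rate chosen so E[depth] ~ log(n)/birth ~ depth
    birth <- log(max(n_otus, 3)) / depth
    tr <- ape::rphylo(n_otus, birth = birth, death = 0)
    tr$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    tr
  })
}

#' Evolve phylogenetically conserved environmental optima
#'
#' Optima are `signal * z + e`, where `z` is a Brownian trait on the tree
#' standardised to unit variance across tips and `e` is i.i.d. standard
#' normal. `signal = 0` therefore yields optima independent of the phylogeny;
#' large `signal` makes trait distance track patristic distance.
#'
#' @param tree a `phylo`.
#' @param signal phylogenetic-signal strength (>= 0).
#' @param seed integer seed or `NULL`.
#' @return named numeric vector of optima, one per tip.
#' @export
simulate_traits <- function(tree, signal = 1, seed = NULL) {
  validate_phylogeny(tree)
  stopifnot(signal >= 0)
  with_seed_or_now(seed, {
    n <- length(tree$tip.label)
    e <- stats::rnorm(n)
    if (signal > 0) {
      z <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      sz <- stats::sd(z)
      if (sz > 0) z <- (z - mean(z)) / sz
      tr <- signal * z + e
    } else {
      tr <- e
    }
    names(tr) <- tree$tip.label
    tr
  })
}

#' Simulate community counts under selection and dispersal regimes
#'
#' Each sample receives a latent environmental value `E_s` (uniform on the
#' configured gradient). The expected relative abundance of OTU `i` in sample
#' `s` is proportional to `m_i * exp(-(opt_i - E_s)^2 / (2 sigma_sel^2))`,
#' where `m` are log-normal metacommunity weights. Under the
#' dispersal-limited regime, samples cycle over `k_pools` source pools whose
#' weights are independent permutations of `m`. Counts are a multinomial draw
#' at the sample's log-normal library size.
#'
#' @param tree a `phylo` over the OTUs.
#' @param traits named optima from [simulate_traits()].
#' @param config a [synth_config()].
#' @param seed integer seed or `NULL` (defaults to `config$seed`).
#' @return list with `table` (an [otu_table()]), `meta` (a `sample_frame`
#'   with design factors, coordinates, environmental variables including the
#'   latent gradient as `temperature`), and `truth` (per-sample pool ids,
#'   `E`, and the regime label).
#' @export
simulate_communities <- function(tree, traits, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  otus <- tree$tip.label
  if (!all(otus %in% names(traits))) stop("traits must cover all tips", call. = FALSE)
  opt <- traits[otus]
  k <- length(otus)
  with_seed_or_now(seed, {
    g <- config$groups
    meta <- do.call(rbind, lapply(seq_len(nrow(g)), function(r) {
      n <- g$n[r]
      sites <- paste0("P", 1 + (seq_len(n) - 1) %% g$n_sites[r])
      data.frame(season = g$season[r], lifestyle = g$lifestyle[r],
                 site = sites,
                 depth = rep_len(c(0, 10, 30, 50, 75, 100, 200), n),
                 stringsAsFactors = FALSE)
    }))
    n_samp <- nrow(meta)
    meta$sample_id <- sprintf("%s_%s_%02d", substr(meta$season, 1, 1),
                              meta$lifestyle, seq_len(n_samp))
    E <- if (config$env_mode == "site_gradient") {
      site_no <- as.integer(sub("P", "", meta$site))
      n_sites <- max(site_no)
      pos <- if (n_sites == 1) 0 else
        -config$env_range + 2 * config$env_range * (site_no - 1) / (n_sites - 1)
      pos + stats::rnorm(n_samp, 0, 0.05 * config$env_range)
    } else {
      stats::runif(n_samp, -config$env_range, config$env_range)
    }
    m <- stats::rlnorm(k, 0, 1)
    pools <- matrix(m, nrow = 1)
    pool_of <- rep(1L, n_samp)
    if (config$dispersal == "limited") {
      pools <- t(vapply(seq_len(config$k_pools),
                        function(p) sample(m), numeric(k)))
      pool_of <- 1L + (seq_len(n_samp) - 1L) %% config$k_pools
    }
    lib <- pmax(50L, as.integer(round(stats::rlnorm(
      n_samp, config$library_meanlog, config$library_sdlog))))
    counts <- matrix(0L, n_samp, k, dimnames = list(meta$sample_id, otus))
    for (s in seq_len(n_samp)) {
      w <- pools[pool_of[s], ]
      if (is.finite(config$sigma_sel)) {
        w <- w * exp(-(opt - E[s])^2 / (2 * config$sigma_sel^2))
      }
      if (sum(w) <= 0) stop("degenerate selection weights", call. = FALSE)
      counts[s, ] <- stats::rmultinom(1, lib[s], w / sum(w))[, 1]
    }
    # latent gradient exposed as a 'temperature'-like measured variable, plus
    # correlated and unrelated covariates to exercise the Mantel/Spearman layer
    meta$longitude <- 122.6 + 0.7 * (as.integer(sub("P", "", meta$site)) - 1)
    meta$latitude <- 31.3 - 0.45 * (as.integer(sub("P", "", meta$site)) - 1)
    meta$temperature <- round(20 + 4 * E + stats::rnorm(n_samp, 0, 0.5), 3)
    meta$salinity <- round(33 + 0.8 * E + stats::rnorm(n_samp, 0, 0.4), 3)
    meta$chla <- round(exp(stats::rnorm(n_samp, 0, 0.8)), 3)
    meta <- meta[, c("sample_id", "season", "lifestyle", "site", "depth",
                     "longitude", "latitude", "temperature", "salinity", "chla")]
    keep <- rowSums(counts) >= 1
    table <- otu_table(counts[keep, , drop = FALSE])
    list(table = table,
         meta = sample_frame(meta[keep, , drop = FALSE]),
         truth = list(regime = if (!is.finite(config$sigma_sel)) {
                        if (config$dispersal == "limited") "dispersal_limited" else "neutral"
                      } else "selection",
                      E = E[keep], pool = pool_of[keep],
                      library_size = lib[keep]))
  })
}

#' Plant correlated OTU blocks into a count table
#'
#' Rebuilds the counts of each block's OTUs from a shared latent log-normal
#' factor: OTU `i` in block `b` gets counts `Poisson(mu_i * exp(s * (sqrt(rho)
#' f_s + sqrt(1-rho) e_is)))` across samples `s`, so every within-block pair
#' shares latent correlation `rho`. OTUs outside blocks are untouched; blocks
#' are disjoint (sampled without replacement, seeded).
#'
#' @param table an [otu_table()].
#' @param blocks list of `list(size =, rho =)`; empty list returns the table
#'   unchanged.
#' @param mean_count target mean count of planted OTUs (scales `mu_i`).
#' @param latent_sd log-scale spread of the shared factor.
#' @param seed integer seed or `NULL`.
#' @return the modified [otu_table()] with attribute `"blocks"`: a list of
#'   character vectors of block OTU ids.
#' @export
plant_correlation_blocks <- function(table, blocks, mean_count = 30,
                                     latent_sd = 1.2, seed = NULL) {
  stopifnot(is_otu_table(table))
  if (length(blocks) == 0L) return(table)
  sizes <- vapply(blocks, `[[`, numeric(1), "size")
  if (sum(sizes) > ncol(table)) stop("blocks exceed available OTUs", call. = FALSE)
  with_seed_or_now(seed, {
    m <- unclass(table)
    chosen <- sample(colnames(m), sum(sizes))
    idx <- split(chosen, rep(seq_along(sizes), sizes))
    n_samp <- nrow(m)
    for (b in seq_along(blocks)) {
      rho <- blocks[[b]]$rho
      f <- stats::rnorm(n_samp)
      a <- sqrt(abs(rho))
      for (o in seq_along(idx[[b]])) {
        otu <- idx[[b]][o]
        # negative rho: alternate the loading sign so adjacent members anti-correlate
        sgn <- if (rho < 0 && o %% 2 == 0) -1 else 1
        e <- stats::rnorm(n_samp)
        lat <- latent_sd * (a * sgn * f + sqrt(1 - abs(rho)) * e)
        mu <- mean_count * exp(lat - latent_sd^2 / 2)
        m[, otu] <- stats::rpois(n_samp, mu)
      }
    }
    out <- otu_table(m)
    attr(out, "blocks") <- unname(lapply(idx, as.character))
    out
  })
}

#' Generate a full synthetic dataset
#'
#' Tree, traits, communities and (optionally) planted correlation blocks in
#' one seeded call; the one-stop entry the pipeline and the validation suite
#' use.
#'
#' @param config a [synth_config()].
#' @return list with `table`, `tree`, `meta`, `traits`, `truth` (including
#'   `blocks`).
#' @export
simulate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  tree <- simulate_tree(config$n_otus, config$tree_depth, seed = config$seed)
  traits <- simulate_traits(tree, config$trait_signal, seed = config$seed + 1L)
  com <- simulate_communities(tree, traits, config, seed = config$seed + 2L)
  table <- com$table
  blocks <- list()
  if (length(config$blocks)) {
    table <- plant_correlation_blocks(table, config$blocks,
                                      seed = config$seed + 3L)
    blocks <- attr(table, "blocks")
  }
  truth <- com$truth
  truth$blocks <- blocks
  list(table = table, tree = tree, meta = com$meta, traits = traits,
       truth = truth)
}
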