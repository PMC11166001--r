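#' Assemble a validated pipeline configuration
#'
#' A run configuration names the inputs (either file paths or a synthetic
#' block handed to [synth_config()]), the rarefaction depth, the assembly and
#' network options, the Mantel variables and the seeds. `run_config()` fills
#' defaults and validates; [run_pipeline()] consumes the result. YAML files
#' with the same structure are accepted everywhere a config is.
#'
#' @param x a named list, a path to a YAML file, or `NULL` for defaults.
#' @return a validated `run_config` list.
#' @export
run_config <- function(x = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  if (is.null(x)) x <- list()
  stopifnot(is.list(x))
  def <- list(
    version = 1,
    inputs = NULL,                     # list(table=, tree=, metadata=)
    synth = NULL,                      # args for synth_config()
    rarefaction = list(depth = "min", seed = 101L),
    assembly = list(n_null = 999L, weighted = TRUE,
                    groups = c("season", "lifestyle"), seed = 202L),
    network = list(min_mean_ra = 1e-4, min_prevalence = 0.20,
                   rho_threshold = 0.7, q_threshold = 0.01,
                   split = c("season", "lifestyle"), seed = 303L),
    stats = list(mantel_vars = c("temperature", "salinity"),
                 n_perm = 999L, seed = 404L),
    anosim = list(groups = c("season", "lifestyle"), n_perm = 999L, seed = 505L),
    out_dir = "microseed-run")
  cfg <- utils::modifyList(def, x)
  if (is.null(cfg$inputs) && is.null(cfg$synth)) {
    stop("config must provide either 'inputs' paths or a 'synth' block", call. = FALSE)
  }
  if (!is.null(cfg$inputs)) {
    for (f in c("table", "tree", "metadata")) {
      p <- cfg$inputs[[f]]
      if (is.null(p)) stop("inputs block lacks '", f, "'", call. = FALSE)
      if (!file.exists(p)) stop("input file not found: ", p, " (", f, ")", call. = FALSE)
    }
  }
  with(cfg$network, stopifnot(rho_threshold > 0, rho_threshold < 1,
                              q_threshold > 0, q_threshold < 1,
                              min_prevalence >= 0, min_prevalence < 1))
  stopifnot(cfg$assembly$n_null >= 99, cfg$stats$n_perm >= 99)
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_done <- function(out_dir, files) all(file.exists(file.path(out_dir, files)))

write_csv_stable <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates validate -> rarefy -> alpha/beta diversity -> ANOSIM ->
#' assembly partition -> co-occurrence networks -> Mantel tests from one
#' configuration, writing every stage's outputs as CSV/TSV/GraphML under
#' `out_dir` plus a machine-readable `manifest.json` (package version, seeds,
#' input checksums, per-stage row counts — no wall-clock entries, so reruns
#' with the same seeds are bit-identical). With `resume = TRUE`, stages whose
#' output files already exist are skipped and marked "resumed" in the
#' manifest.
#'
#' @param config a `run_config`, a named list, or a YAML path.
#' @param resume skip stages whose outputs already exist.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "microseed",
                   version = as.character(utils::packageVersion("microseed")),
                   config = unclass(cfg), stages = list())
  note <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status), list(...))
    message("[", stage, "] ", status)
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    synth_args <- cfg$synth
    if (!is.null(synth_args$groups) && !is.data.frame(synth_args$groups)) {
      synth_args$groups <- as.data.frame(synth_args$groups,
                                         stringsAsFactors = FALSE)
    }
    if (!is.null(synth_args$blocks)) {
      synth_args$blocks <- lapply(synth_args$blocks, as.list)
    }
    scfg <- do.call(synth_config, synth_args)
    if (resume && stage_done(out, c("table.tsv", "tree.nwk", "meta.tsv"))) {
      table <- read_otu_table(file.path(out, "table.tsv"), "samples_rows")
      tree <- read_newick(file.path(out, "tree.nwk"))
      meta <- read_metadata(file.path(out, "meta.tsv"))
      note("synth", "resumed")
    } else {
      ds <- simulate_dataset(scfg)
      table <- ds$table; tree <- ds$tree; meta <- ds$meta
      write_otu_table(table, file.path(out, "table.tsv"))
      ape::write.tree(tree, file.path(out, "tree.nwk"))
      utils::write.table(as.data.frame(meta), file.path(out, "meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      truth <- ds$truth
      truth$blocks <- lapply(truth$blocks, as.character)
      jsonlite::write_json(truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      note("synth", "computed", n_samples = nrow(table), n_otus = ncol(table))
    }
  } else {
    table <- read_otu_table(cfg$inputs$table,
                            orientation = cfg$inputs$orientation %||% "samples_rows")
    tree <- read_newick(cfg$inputs$tree)
    meta <- read_metadata(cfg$inputs$metadata)
    note("read", "computed", n_samples = nrow(table), n_otus = ncol(table))
  }
  al <- align_data(table, tree, meta)
  table <- al$table; tree <- al$tree; meta <- al$meta
  checks <- c(table = digest_table(table))
  note("align", "computed", n_samples = nrow(table), n_otus = ncol(table),
       checksum = unname(checks))

  # --- rarefaction ----------------------------------------------------------
  rare_path <- file.path(out, "rarefied.tsv")
  if (resume && file.exists(rare_path)) {
    rtab <- read_otu_table(rare_path, "samples_rows")
    note("rarefy", "resumed")
  } else {
    rtab <- rarefy_table(table, depth = cfg$rarefaction$depth,
                         seed = cfg$rarefaction$seed)
    write_otu_table(rtab, rare_path)
    note("rarefy", "computed", depth = min(rowSums(rtab)), n_samples = nrow(rtab))
  }
  meta <- meta[match(rownames(rtab), meta$sample_id), , drop = FALSE]
  class(meta) <- c("sample_frame", "data.frame")

  # --- diversity ------------------------------------------------------------
  if (resume && stage_done(out, c("alpha.csv", "braycurtis.csv", "anosim.csv"))) {
    bc <- stats::as.dist(as.matrix(utils::read.csv(
      file.path(out, "braycurtis.csv"), row.names = 1, check.names = FALSE)))
    note("diversity", "resumed")
  } else {
    alpha <- alpha_diversity(rtab)
    write_csv_stable(alpha, file.path(out, "alpha.csv"))
    bc <- bray_curtis(rtab)
    bm <- as.matrix(bc)
    utils::write.csv(data.frame(sample_id = rownames(bm),
                                format(bm, digits = 12, trim = TRUE),
                                check.names = FALSE),
                     file.path(out, "braycurtis.csv"), row.names = FALSE)
    an <- lapply(cfg$anosim$groups[cfg$anosim$groups %in% names(meta)],
                 function(g) {
                   res <- anosim_test(bc, meta[[g]], n_perm = cfg$anosim$n_perm,
                                      seed = cfg$anosim$seed)
                   data.frame(grouping = g, R = res$statistic, p = res$p_value,
                              n_perm = res$n_perm)
                 })
    write_csv_stable(do.call(rbind, an), file.path(out, "anosim.csv"))
    note("diversity", "computed", n_samples = nrow(rtab))
  }

  # --- assembly partition ---------------------------------------------------
  if (resume && stage_done(out, c("pairs.csv", "fractions.csv"))) {
    note("assembly", "resumed")
  } else {
    strat <- interaction(meta[cfg$assembly$groups], sep = "_", drop = TRUE)
    part <- assembly_partition(rtab, tree, strat,
                               n_null = cfg$assembly$n_null,
                               weighted = cfg$assembly$weighted,
                               seed = cfg$assembly$seed)
    write_csv_stable(part$pairs, file.path(out, "pairs.csv"))
    write_csv_stable(part$fractions, file.path(out, "fractions.csv"))
    note("assembly", "computed", n_pairs = nrow(part$pairs),
         n_undefined = sum(part$fractions$n_undefined))
  }

  # --- networks -------------------------------------------------------------
  if (resume && stage_done(out, "topology.csv")) {
    note("network", "resumed")
  } else {
    sn <- split_networks(rtab, meta, split_cols = cfg$network$split,
                         seed = cfg$network$seed,
                         min_mean_ra = cfg$network$min_mean_ra,
                         min_prevalence = cfg$network$min_prevalence,
                         rho_threshold = cfg$network$rho_threshold,
                         q_threshold = cfg$network$q_threshold)
    keys <- list()
    for (nm in names(sn$networks)) {
      net <- sn$networks[[nm]]
      write_network(net, file.path(out, paste0("network_", nm, ".graphml")),
                    "graphml")
      write_network(net, file.path(out, paste0("network_", nm, ".edges.tsv")),
                    "edgelist")
      if (nrow(net$nodes) >= 5) {
        ks <- keystone_taxa(net)
        if (length(ks$keystones)) {
          keys[[nm]] <- cbind(stratum = nm,
                              ks$table[ks$table$keystone,
                                       c("otu", "degree", "betweenness")])
        }
      }
    }
    write_csv_stable(sn$topology, file.path(out, "topology.csv"))
    kdf <- if (length(keys)) do.call(rbind, keys) else
      data.frame(stratum = character(), otu = character(),
                 degree = integer(), betweenness = numeric())
    write_csv_stable(kdf, file.path(out, "keystones.csv"))
    note("network", "computed", n_networks = length(sn$networks),
         n_keystones = nrow(kdf))
  }

  # --- environmental statistics ---------------------------------------------
  if (resume && stage_done(out, "mantel.csv")) {
    note("stats", "resumed")
  } else {
    vars <- intersect(cfg$stats$mantel_vars, names(meta))
    mt <- lapply(vars, function(v) {
      ed <- env_distance(meta, v)
      res <- mantel_test(bc, ed, n_perm = cfg$stats$n_perm, seed = cfg$stats$seed)
      data.frame(variable = v, r = res$r, p = res$p_value, n_perm = res$n_perm)
    })
    write_csv_stable(do.call(rbind, mt), file.path(out, "mantel.csv"))
    note("stats", "computed", n_variables = length(vars))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

digest_table <- function(table) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_otu_table(table, tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
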