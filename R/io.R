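#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream phylogenetic
#' null models need: a single tree, unique tip labels, and a branch length on
#' every edge (all non-negative). The tree is not required to be ultrametric
#' or rooted in the strict bifurcating sense; patristic distances are
#' well-defined either way.
#'
#' @param path path to a newick file (one tree).
#' @param text optional newick string instead of a file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr)) stop("unparseable newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    stop("file contains more than one tree", call. = FALSE)
  }
  validate_phylogeny(tr)
  tr
}

validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylogeny", call. = FALSE)
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate tip label: '", dup[1], "'", call. = FALSE)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("missing branch length(s): every edge must carry a length", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length", call. = FALSE)
  invisible(tr)
}

#' Patristic (cophenetic) distances between tips
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix of tip-to-tip branch-length distances.
#' @export
patristic <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

#' Read per-sample metadata from TSV
#'
#' The file must name a sample-id column (first column or `sample_id`) and
#' the design factors `season` (summer/winter) and `lifestyle` (FL =
#' free-living, PA = particle-associated). Any further columns are carried
#' along; numeric ones are treated as environmental variables (temperature,
#' salinity, pH, DO, Chl a, nutrients, ...). Missing environmental values are
#' allowed and propagate as `NA`.
#'
#' @param path path to a TSV file.
#' @return a `sample_frame`: a data.frame with columns `sample_id`, `season`,
#'   `lifestyle`, optional `site`/`depth`/coordinates, and environmental
#'   variables; attribute `"env_vars"` lists the numeric variable names.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_frame(df)
}

#' Validate a metadata data.frame
#'
#' @param df data.frame with at least `sample_id` (or sample ids in the first
#'   column), `season`, `lifestyle`.
#' @return validated `sample_frame` (see [read_metadata()]).
#' @export
sample_frame <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id in metadata: '", dup[1], "'", call. = FALSE)
  for (col in c("season", "lifestyle")) {
    if (!col %in% names(df)) stop("metadata lacks required column '", col, "'", call. = FALSE)
  }
  bad <- setdiff(unique(df$season), c("summer", "winter"))
  if (length(bad)) stop("season outside {summer, winter}: '", bad[1], "'", call. = FALSE)
  bad <- setdiff(unique(df$lifestyle), c("FL", "PA"))
  if (length(bad)) stop("lifestyle outside {FL, PA}: '", bad[1], "'", call. = FALSE)
  reserved <- c("sample_id", "season", "lifestyle", "site")
  env <- names(df)[vapply(df, is.numeric, logical(1)) & !names(df) %in% reserved]
  attr(df, "env_vars") <- env
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Align an OTU table, a phylogeny and sample metadata
#'
#' Restricts the OTU axis to the intersection of table OTU ids and tree tips
#' (pruning the tree accordingly), and the sample axis to samples present in
#' the metadata. Dropped identifiers are reported via `message()`. The
#' operation is idempotent.
#'
#' @param table an [otu_table()].
#' @param tree a `phylo` whose tips are OTU ids, or `NULL` to skip the OTU
#'   axis.
#' @param meta a `sample_frame`, or `NULL` to skip the sample axis.
#' @return list with elements `table`, `tree`, `meta`, aligned to common ids
#'   (input order of the table preserved).
#' @export
align_data <- function(table, tree = NULL, meta = NULL) {
  stopifnot(is_otu_table(table))
  if (!is.null(tree)) {
    validate_phylogeny(tree)
    keep_otus <- intersect(colnames(table), tree$tip.label)
    if (length(keep_otus) == 0L) {
      stop("no OTUs shared between table and tree", call. = FALSE)
    }
    drop_t <- setdiff(colnames(table), keep_otus)
    drop_tr <- setdiff(tree$tip.label, keep_otus)
    if (length(drop_t)) message(length(drop_t), " OTU(s) dropped from table (absent from tree)")
    if (length(drop_tr)) message(length(drop_tr), " tip(s) pruned from tree (absent from table)")
    table <- table[, keep_otus, drop = FALSE]
    if (length(drop_tr)) tree <- ape::drop.tip(tree, drop_tr)
  }
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "sample_frame"))
    keep_s <- intersect(rownames(table), meta$sample_id)
    if (length(keep_s) == 0L) {
      stop("no samples shared between table and metadata", call. = FALSE)
    }
    drop_s <- setdiff(rownames(table), keep_s)
    drop_m <- setdiff(meta$sample_id, keep_s)
    if (length(drop_s)) message(length(drop_s), " sample(s) dropped from table (absent from metadata)")
    if (length(drop_m)) warning(length(drop_m), " metadata row(s) unmatched in table", call. = FALSE)
    table <- table[keep_s, , drop = FALSE]
    meta <- meta[match(keep_s, meta$sample_id), , drop = FALSE]
    class(meta) <- c("sample_frame", "data.frame")
  }
  empty <- rowSums(table) < 1
  if (any(empty)) {
    message(sum(empty), " empty sample(s) dropped after OTU alignment")
    table <- table[!empty, , drop = FALSE]
    if (!is.null(meta)) {
      meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
      class(meta) <- c("sample_frame", "data.frame")
    }
  }
  list(table = table, tree = tree, meta = meta)
}

#' Export a co-occurrence network to disk
#'
#' Nodes carry mean relative abundance, prevalence and (if supplied at build
#' time) a taxonomy string; edges carry the Spearman coefficient, its
#' BH-adjusted p-value and the sign.
#'
#' @param net a `cooc_network` (see [build_network()]).
#' @param path output path.
#' @param format one of `"graphml"`, `"gml"`, `"edgelist"` (tab-separated
#'   with a header).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "gml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooc_network"))
  if (format == "edgelist") {
    ed <- net$edges
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = format)
  }
  invisible(path)
}
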