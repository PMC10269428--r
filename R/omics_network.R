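#' Correlation-network configuration
#'
#' @param rho_cutoff Absolute Spearman correlation threshold for keeping an
#'   edge (default 0.6).
#' @param top_k Number of top-ranked features taken from each modality as
#'   candidate nodes (default 20).
#' @return A `network_config` list.
#' @export
network_config <- function(rho_cutoff = 0.6, top_k = 20) {
  cfg <- list(rho_cutoff = as.numeric(rho_cutoff), top_k = as.integer(top_k))
  if (cfg$rho_cutoff <= 0 || cfg$rho_cutoff >= 1)
    stop("rho_cutoff must lie in (0, 1)", call. = FALSE)
  if (cfg$top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  structure(cfg, class = "network_config")
}

#' Build the cross-omics Spearman correlation network
#'
#' Integrates the top-ranked features of the three modalities: candidate
#' nodes are the union of each modality's `top_k` features, subjects are
#' aligned by intersection across modalities, and every pairwise Spearman
#' correlation of delta values (within- and cross-modality) is computed.
#' An undirected edge is kept when `|rho| >= rho_cutoff`; isolated
#' candidates remain as degree-0 nodes.
#'
#' @param deltas Named list of `delta_matrix` objects (one per modality).
#' @param ranked Named list (same names) of ranked features: the data frame
#'   from [rank_importance()] or a character vector of feature ids.
#' @param config A [network_config()].
#' @return Class `omics_network`: `nodes` (feature, modality, degree),
#'   `edges` (source, target, rho, p, modality_source, modality_target),
#'   `subjects`, `config`.
#' @export
build_network <- function(deltas, ranked, config = network_config()) {
  stopifnot(inherits(config, "network_config"),
            is.list(deltas), is.list(ranked),
            all(names(ranked) %in% names(deltas)))
  subjects <- Reduce(intersect, lapply(deltas, function(d) rownames(d$values)))
  if (length(subjects) < 3L)
    stop("fewer than 3 subjects align across modalities", call. = FALSE)
  dropped <- setdiff(unique(unlist(lapply(deltas, function(d)
    rownames(d$values)))), subjects)
  if (length(dropped))
    message("build_network: dropping unaligned subject(s): ",
            paste(dropped, collapse = ", "))

  cols <- list(); modality <- character(0)
  for (m in names(ranked)) {
    feats <- ranked[[m]]
    if (is.data.frame(feats)) feats <- feats$feature
    feats <- utils::head(feats, config$top_k)
    missing <- setdiff(feats, colnames(deltas[[m]]$values))
    if (length(missing))
      stop("ranked feature(s) absent from ", m, " deltas: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    cols[[m]] <- deltas[[m]]$values[subjects, feats, drop = FALSE]
    modality <- c(modality, stats::setNames(rep(m, length(feats)), feats))
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- unlist(lapply(cols, colnames), use.names = FALSE)

  nodes <- colnames(mat)
  ee <- utils::combn(length(nodes), 2L)
  src <- nodes[ee[1L, ]]; tgt <- nodes[ee[2L, ]]
  rho <- numeric(ncol(ee)); p <- numeric(ncol(ee))
  for (i in seq_len(ncol(ee))) {
    r <- suppressWarnings(spearman_rank(mat[, ee[1L, i]], mat[, ee[2L, i]]))
    rho[i] <- r$rho; p[i] <- r$p
  }
  keep <- !is.na(rho) & abs(rho) >= config$rho_cutoff
  edges <- data.frame(source = src[keep], target = tgt[keep],
                      rho = rho[keep], p = p[keep],
                      modality_source = unname(modality[src[keep]]),
                      modality_target = unname(modality[tgt[keep]]),
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$source, edges$target), levels = nodes))
  node_df <- data.frame(feature = nodes, modality = unname(modality[nodes]),
                        degree = as.integer(deg[nodes]),
                        stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = edges, subjects = subjects,
                 config = config),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("omics_network: %d nodes (%s), %d edges at |rho| >= %.2f, n = %d subjects\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(table(x$nodes$modality)),
                            table(x$nodes$modality)), collapse = ", "),
              nrow(x$edges), x$config$rho_cutoff, length(x$subjects)))
  invisible(x)
}

#' Convert an `omics_network` to an igraph graph
#' @param net An `omics_network`.
#' @return An undirected `igraph` graph with node attributes `modality`,
#'   `degree` and edge attributes `rho`, `p`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @export
plot.omics_network <- function(x, ...) {
  g <- as_igraph(x)
  pal <- c(microbiome = "#4daf4a", metabolome = "#ff7f00",
           methylome = "#377eb8")
  igraph::plot.igraph(
    g,
    vertex.color = pal[igraph::V(g)$modality],
    vertex.size = 5 + 2 * igraph::V(g)$degree,
    vertex.label.cex = 0.6,
    edge.width = 3 * abs(igraph::E(g)$rho),
    edge.color = ifelse(igraph::E(g)$rho > 0, "#2166ac", "#b2182b"), ...)
  invisible(x)
}

#' Export / import a correlation network
#'
#' Writes the edge list as TSV (source, target, rho, p, modality_source,
#' modality_target) and the full graph as GraphML with node attributes
#' `modality` and `degree` and edge attributes `rho` and `p`.
#'
#' @param net An `omics_network`.
#' @param edge_tsv,graphml Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, edge_tsv = NULL, graphml = NULL) {
  stopifnot(inherits(net, "omics_network"))
  if (!is.null(edge_tsv))
    utils::write.table(net$edges, edge_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  invisible(c(edge_tsv = edge_tsv, graphml = graphml))
}

#' @rdname export_network
#' @param path GraphML path to read back.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
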