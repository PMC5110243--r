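#' Build the thresholded intercellular correlation network
#'
#' Cells are vertices; an undirected edge connects two cells iff the Pearson
#' correlation of their expression over the informative-gene subset exceeds
#' `tau` (the lineage-network convention: tau = 0.4). Edge weights store the
#' correlation. Cells constant over the subset are excluded (logged).
#'
#' @param m An `ExpressionMatrix` (log2p1), >= 2 cells.
#' @param genes Informative gene subset (default: all genes).
#' @param tau Correlation threshold (exclusive; default 0.4).
#' @return A `LineageGraph`: list with `graph` (igraph), `tau`, `excluded`.
#' @export
build_network <- function(m, genes = NULL, tau = 0.4) {
  assert_log2p1(m)
  v <- m$values
  if (nrow(v) < 2) stop("need >= 2 cells")
  if (!is.null(genes)) {
    genes <- intersect(genes, colnames(v))
    if (length(genes) == 0) stop("no subset genes present in the matrix")
    v <- v[, genes, drop = FALSE]
  }
  sds <- apply(v, 1, stats::sd)
  excluded <- rownames(v)[sds == 0]
  if (length(excluded)) {
    message(length(excluded), " constant cells excluded from the network: ",
            paste(utils::head(excluded, 5), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(v))
  ut <- which(upper.tri(cc) & cc > tau, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(cc)[ut[, 1]],
    to = rownames(cc)[ut[, 2]],
    weight = cc[ut],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(cc), stringsAsFactors = FALSE)
  )
  structure(list(graph = g, tau = tau, excluded = excluded), class = "LineageGraph")
}

#' @export
print.LineageGraph <- function(x, ...) {
  cat(sprintf("LineageGraph: %d cells, %d edges (rho > %.2f)%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$tau,
              if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

#' Edge list of a lineage graph
#'
#' @param lg A `LineageGraph`.
#' @return data.frame `cell_i`, `cell_j`, `weight`.
#' @export
edge_table <- function(lg) {
  if (!inherits(lg, "LineageGraph")) stop("expected a LineageGraph")
  e <- igraph::as_data_frame(lg$graph, what = "edges")
  names(e) <- c("cell_i", "cell_j", "weight")
  e
}

#' Minimum-spanning-tree pseudotime ordering
#'
#' Builds the complete graph over cells with distance 1 - Pearson correlation
#' (over the gene subset), takes its minimum spanning tree, extracts the tree
#' diameter (the longest shortest path) as the lineage backbone, projects
#' every remaining cell onto its nearest backbone node, and orders cells by
#' their projected position along the backbone. The ordering is defined up to
#' global reversal. Equal-weight edges are tie-broken by the lexicographic
#' cell-id pair (an epsilon far below correlation resolution).
#'
#' @param m An `ExpressionMatrix` (log2p1).
#' @param genes Gene subset for the correlations (default: all genes).
#' @return A `PseudotimeOrder`: data.frame with `cell_id`, `position`
#'   (cumulative backbone distance of the projection target) and `backbone`,
#'   ordered along the backbone.
#' @export
mst_pseudotime <- function(m, genes = NULL) {
  assert_log2p1(m)
  v <- m$values
  if (!is.null(genes)) {
    genes <- intersect(genes, colnames(v))
    if (length(genes) == 0) stop("no subset genes present in the matrix")
    v <- v[, genes, drop = FALSE]
  }
  cells <- rownames(v)
  if (nrow(v) < 3) {
    out <- data.frame(cell_id = sort(cells), position = 0, backbone = TRUE,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("PseudotimeOrder", "data.frame")))
  }
  cc <- suppressWarnings(stats::cor(t(v)))
  diag(cc) <- 1
  bad <- rownames(cc)[apply(cc, 1, anyNA)]
  if (length(bad)) {
    warning(length(bad), " cells with undefined correlations removed: ",
            paste(utils::head(bad, 5), collapse = ", "))
    keep <- setdiff(rownames(cc), bad)
    cc <- cc[keep, keep, drop = FALSE]
  }
  ids <- rownames(cc)
  n <- length(ids)
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  ed <- data.frame(
    from = ids[pairs[, 1]], to = ids[pairs[, 2]],
    weight = 1 - cc[pairs], stringsAsFactors = FALSE
  )
  # lexicographic tie-break for equal-weight edges
  key <- ifelse(ed$from < ed$to, paste(ed$from, ed$to), paste(ed$to, ed$from))
  ed$weight <- ed$weight + rank(key) * 1e-12
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = ids))
  mt <- igraph::mst(g, weights = igraph::E(g)$weight)

  comp <- igraph::components(mt)
  if (comp$no > 1) warning("graph is disconnected; ordering per component")
  out <- list()
  offset <- 0
  comp_order <- order(-tabulate(comp$membership))
  for (ci in comp_order) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(mt, vs)
    sub_ids <- igraph::V(sub)$name
    if (length(sub_ids) == 1) {
      out[[length(out) + 1]] <- data.frame(cell_id = sub_ids, position = offset,
                                           backbone = TRUE, stringsAsFactors = FALSE)
      offset <- offset + 1
      next
    }
    diam <- igraph::get_diameter(sub, weights = igraph::E(sub)$weight)
    bb <- igraph::V(sub)$name[diam]
    step <- numeric(length(bb))
    if (length(bb) > 1) {
      for (k in 2:length(bb)) step[k] <- 1 - cc[bb[k - 1], bb[k]]
    }
    pos_bb <- stats::setNames(cumsum(step), bb)
    others <- setdiff(sub_ids, bb)
    pos <- pos_bb
    if (length(others)) {
      dm <- igraph::distances(sub, v = others, to = bb,
                              weights = igraph::E(sub)$weight)
      nearest <- bb[apply(dm, 1, which.min)]
      pos <- c(pos, stats::setNames(pos_bb[nearest], others))
    }
    df <- data.frame(cell_id = names(pos), position = unname(pos) + offset,
                     backbone = names(pos) %in% bb, stringsAsFactors = FALSE)
    df <- df[order(df$position, !df$backbone, df$cell_id), ]
    out[[length(out) + 1]] <- df
    offset <- offset + max(df$position) + 1
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("PseudotimeOrder", "data.frame"))
}
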