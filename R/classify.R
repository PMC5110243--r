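#' Four-zone bulk reference profiles
#'
#' @param profiles Numeric matrix with rows `VZ`, `iSVZ`, `oSVZ`, `CP` and one
#'   column per gene: the mean expression of each gene in each germinal-zone
#'   bulk sample.
#' @return A `ZoneReference`.
#' @export
zone_reference <- function(profiles) {
  zones <- c("VZ", "iSVZ", "oSVZ", "CP")
  if (!is.matrix(profiles) || !identical(rownames(profiles), zones)) {
    stop("profiles must be a matrix with rows VZ, iSVZ, oSVZ, CP")
  }
  if (is.null(colnames(profiles))) stop("profiles must carry gene ids as colnames")
  structure(list(profiles = profiles), class = "ZoneReference")
}

#' Labelled fetal reference cells
#'
#' Reference single-cell profiles with known cell types. Subtype labels
#' (e.g. "AP1", "BP2", "N3" — type by cycle phase or maturation stage) are
#' collapsed to AP/BP/N by stripping the trailing digits.
#'
#' @param m An `ExpressionMatrix` (log2p1) of the reference cells.
#' @param cell_types Character vector (named by cell id, or in matrix row
#'   order) of types or subtypes.
#' @return A `FetalReference`: list with `matrix` (cells sorted by id) and
#'   `type` (collapsed labels).
#' @export
fetal_reference <- function(m, cell_types) {
  assert_log2p1(m)
  cells <- rownames(m$values)
  if (!is.null(names(cell_types))) {
    if (!setequal(names(cell_types), cells)) stop("cell_types names must match cell ids")
    cell_types <- cell_types[cells]
  } else if (length(cell_types) != length(cells)) {
    stop("cell_types must have one label per reference cell")
  }
  collapsed <- sub("[0-9]+$", "", as.character(cell_types))
  bad <- setdiff(unique(collapsed), c("AP", "BP", "N"))
  if (length(bad)) stop("unknown cell type label: ", bad[1])
  if (!all(c("AP", "BP", "N") %in% collapsed)) {
    stop("reference must contain at least one cell of each collapsed type")
  }
  ord <- order(cells)  # deterministic tie-break: lowest reference cell id
  structure(list(
    matrix = expression_matrix(m$values[ord, , drop = FALSE], m$scale),
    type = stats::setNames(collapsed[ord], cells[ord])
  ), class = "FetalReference")
}

#' Assign cells to germinal zones by Spearman correlation
#'
#' Each cell's transcriptome is Spearman-correlated with the four zone bulk
#' profiles over the shared genes; the assigned zone is the argmax. The four
#' correlations are also z-scaled within each cell (mean-centred, divided by
#' the sd) for display — scaling does not change the argmax. Cells (or
#' profiles) with undefined correlations are flagged `unassigned`.
#'
#' @param m An `ExpressionMatrix` (log2p1).
#' @param ref A [zone_reference()].
#' @return data.frame with `cell_id`, raw correlations `rho_VZ..rho_CP`,
#'   scaled `z_VZ..z_CP`, and `zone`.
#' @export
zone_assign <- function(m, ref) {
  assert_log2p1(m)
  if (!inherits(ref, "ZoneReference")) stop("expected a ZoneReference")
  shared <- intersect(colnames(m$values), colnames(ref$profiles))
  dropped <- ncol(m$values) - length(shared)
  if (dropped > 0) message(dropped, " query genes absent from the zone reference were dropped")
  if (length(shared) < 10) stop("need >= 10 shared genes between matrix and reference")
  rho <- suppressWarnings(stats::cor(
    t(m$values[, shared, drop = FALSE]),
    t(ref$profiles[, shared, drop = FALSE]),
    method = "spearman"
  ))
  zones <- rownames(ref$profiles)
  colnames(rho) <- zones
  zscaled <- t(apply(rho, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(NA_real_, length(r)) else (r - mean(r)) / s
  }))
  zone <- apply(rho, 1, function(r) {
    if (anyNA(r)) "unassigned" else zones[which.max(r)]
  })
  out <- data.frame(cell_id = rownames(m$values), stringsAsFactors = FALSE)
  out[paste0("rho_", zones)] <- rho
  out[paste0("z_", zones)] <- zscaled
  out$zone <- zone
  out
}

#' Assign cell types by maximum correlation with reference cells
#'
#' Each query cell is Pearson-correlated with every labelled reference cell
#' over the given gene subset and assigned the collapsed type (AP/BP/N) of the
#' best-correlating reference cell. Ties are broken deterministically toward
#' the lowest reference cell id, with a warning.
#'
#' @param m An `ExpressionMatrix` (log2p1).
#' @param ref A [fetal_reference()].
#' @param genes Gene subset used for the correlation (default: all shared).
#' @return data.frame with `cell_id`, `assigned_type`, `best_ref`, `max_cor`.
#' @export
celltype_assign <- function(m, ref, genes = NULL) {
  assert_log2p1(m)
  if (!inherits(ref, "FetalReference")) stop("expected a FetalReference")
  if (is.null(genes)) genes <- colnames(ref$matrix$values)
  shared <- Reduce(intersect, list(genes, colnames(m$values), colnames(ref$matrix$values)))
  if (length(shared) == 0) stop("empty gene intersection between query, reference and subset")
  n_dropped <- length(genes) - length(shared)
  if (n_dropped > 0) message(n_dropped, " subset genes missing from query or reference were dropped")
  cc <- suppressWarnings(stats::cor(
    t(m$values[, shared, drop = FALSE]),
    t(ref$matrix$values[, shared, drop = FALSE])
  ))
  n_ties <- 0L
  res <- apply(cc, 1, function(r) {
    if (anyNA(r)) return(c(NA_character_, NA_character_, NA_character_))
    mx <- max(r)
    hits <- which(r == mx)
    if (length(hits) > 1) n_ties <<- n_ties + 1L
    best <- colnames(cc)[hits[1]]  # reference columns are sorted by id
    c(unname(ref$type[best]), best, format(mx, digits = 17))
  })
  if (n_ties > 0) warning(n_ties, " cells had tied argmax correlations; lowest reference id used")
  data.frame(
    cell_id = rownames(m$values),
    assigned_type = ifelse(is.na(res[1, ]), "unassigned", res[1, ]),
    best_ref = res[2, ],
    max_cor = as.numeric(res[3, ]),
    stringsAsFactors = FALSE
  )
}

#' Assign cell-cycle phase by hierarchical clustering on G2M genes
#'
#' Cells of one class are hierarchically clustered (correlation distance
#' 1 - Pearson, Ward linkage) on the G2M gene panel and the tree cut into
#' three clusters: highest mean G2M expression -> `G2M`, lowest -> `G1`,
#' middle -> `intermediate` (conventionally excluded from differential
#' expression). Fewer than three distinct expression patterns make every cell
#' `intermediate`.
#'
#' @param m An `ExpressionMatrix` (log2p1), restricted to one cell class.
#' @param g2m_genes Gene panel marking G2M (>= 5 must be present); typically
#'   the top PC1-correlating genes of a proliferating-progenitor reference.
#' @return data.frame with `cell_id` and `phase`.
#' @export
cycle_assign <- function(m, g2m_genes) {
  assert_log2p1(m)
  v <- m$values
  if (nrow(v) < 6) stop("need >= 6 cells")
  present <- intersect(g2m_genes, colnames(v))
  if (length(present) < 5) stop("need >= 5 g2m genes present in the matrix")
  sub <- v[, present, drop = FALSE]
  phase <- rep("intermediate", nrow(v))
  if (nrow(unique(sub)) >= 3) {
    cc <- suppressWarnings(stats::cor(t(sub)))
    cc[is.na(cc)] <- 0
    # Ward linkage: average linkage chains the two phase clusters together
    # whenever the panel's G2M amplitude profile is near-collinear with its
    # baseline profile, making a forced 3-cut collapse; Ward is robust here
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
    cl <- stats::cutree(hc, k = 3)
    cl_mean <- tapply(rowMeans(sub), cl, mean)
    phase[cl == names(which.max(cl_mean))] <- "G2M"
    phase[cl == names(which.min(cl_mean))] <- "G1"
  }
  data.frame(cell_id = rownames(v), phase = phase, stringsAsFactors = FALSE)
}
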