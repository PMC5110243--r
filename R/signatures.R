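#' Derive NSPC and neuron signatures from PC1 of a reference matrix
#'
#' Runs PCA on the (filtered) reference matrix — genes centered, not scaled —
#' and correlates each gene's expression with the PC1 cell scores. The top
#' `n_top` genes by Pearson correlation form the NSPC signature, the bottom
#' `n_top` the neuron signature. PCA sign is arbitrary; if `orient_genes` is
#' given, PC1 is flipped so their mean correlation is positive (so known
#' proliferation markers load positive).
#'
#' @param reference An `ExpressionMatrix` (log2p1), already through
#'   [filter_genes()]; at least 3 cells.
#' @param n_top Genes per signature (default 100).
#' @param orient_genes Optional marker gene ids fixing the PC1 orientation.
#' @return A `SignatureSet`: list with `nspc_genes` (descending correlation),
#'   `neuron_genes` (ascending), `pc1_gene_correlations`, `pc1_cell_scores`,
#'   `pc1_rotation` and `gene_centers` (for projecting query cells).
#' @export
pc1_signatures <- function(reference, n_top = 100, orient_genes = NULL) {
  assert_log2p1(reference)
  v <- reference$values
  if (nrow(v) < 3) stop("need >= 3 reference cells")
  if (n_top > ncol(v)) stop("n_top exceeds gene count")
  if (2 * n_top > ncol(v)) stop("2 * n_top exceeds gene count; signatures would overlap")
  pca <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1]
  if (stats::sd(scores) == 0) stop("PC1 undefined: reference matrix is constant")
  cors <- suppressWarnings(drop(stats::cor(v, scores)))
  rot <- pca$rotation[, 1]
  if (!is.null(orient_genes)) {
    og <- intersect(orient_genes, names(cors))
    if (length(og) == 0) stop("none of orient_genes present in the reference")
    if (mean(cors[og], na.rm = TRUE) < 0) {
      scores <- -scores
      cors <- -cors
      rot <- -rot
    }
  }
  ranked <- names(sort(cors[!is.na(cors)], decreasing = TRUE))
  if (length(ranked) < 2 * n_top) stop("not enough genes with defined PC1 correlation")
  structure(list(
    nspc_genes = ranked[seq_len(n_top)],
    neuron_genes = rev(ranked)[seq_len(n_top)],
    pc1_gene_correlations = cors,
    pc1_cell_scores = scores,
    pc1_rotation = rot,
    gene_centers = pca$center
  ), class = "SignatureSet")
}

#' Score one cell for the NSPC and neuron signatures
#'
#' A cell's score for a signature is the number of signature genes expressed
#' above `threshold`, divided by the number of *all* genes expressed above
#' `threshold` in that cell. With no gene above threshold the scores are
#' undefined (`NA`), not 0.
#'
#' @param cell Named numeric vector of log2(FPKM+1) values for one cell.
#' @param sig A `SignatureSet` from [pc1_signatures()].
#' @param threshold Expression cutoff (default 5.0, i.e. log2 FPKM of 5).
#' @return List with `nspc_score`, `neuron_score` (each in \[0,1\] or `NA`)
#'   and `n_expressed` (the denominator).
#' @export
signature_score <- function(cell, sig, threshold = 5.0) {
  if (is.null(names(cell))) stop("cell vector must be named by gene id")
  expressed <- names(cell)[!is.na(cell) & cell > threshold]
  n <- length(expressed)
  if (n == 0) {
    return(list(nspc_score = NA_real_, neuron_score = NA_real_, n_expressed = 0L))
  }
  list(
    nspc_score = sum(expressed %in% sig$nspc_genes) / n,
    neuron_score = sum(expressed %in% sig$neuron_genes) / n,
    n_expressed = n
  )
}

#' Score every cell of a matrix for the signatures
#'
#' Vectorized [signature_score()] plus each cell's projection onto the
#' reference PC1 axis (over the genes shared with the reference).
#'
#' @inheritParams signature_score
#' @param m An `ExpressionMatrix` (log2p1).
#' @return data.frame with `cell_id`, `nspc_score`, `neuron_score`,
#'   `n_expressed`, `pc1_position`.
#' @export
signature_scores <- function(m, sig, threshold = 5.0) {
  assert_log2p1(m)
  v <- m$values
  expressed <- v > threshold
  denom <- rowSums(expressed)
  nspc <- rowSums(expressed[, colnames(v) %in% sig$nspc_genes, drop = FALSE])
  neur <- rowSums(expressed[, colnames(v) %in% sig$neuron_genes, drop = FALSE])
  shared <- intersect(colnames(v), names(sig$pc1_rotation))
  pc1 <- as.numeric(
    sweep(v[, shared, drop = FALSE], 2, sig$gene_centers[shared]) %*%
      sig$pc1_rotation[shared]
  )
  data.frame(
    cell_id = rownames(v),
    nspc_score = ifelse(denom > 0, nspc / denom, NA_real_),
    neuron_score = ifelse(denom > 0, neur / denom, NA_real_),
    n_expressed = denom,
    pc1_position = pc1,
    stringsAsFactors = FALSE
  )
}

#' Select population-defining genes from the leading principal components
#'
#' For each of the first `n_pcs` PCs, gene loadings are tested with a
#' permutation test: cell labels are shuffled and the loading magnitude
#' recomputed, giving a per-gene Monte-Carlo p-value (plain k/B estimator).
#' Genes with p < `p_cut` are kept, at most `max_per_pc` per PC (ranked by
#' loading magnitude); the union over PCs is returned.
#'
#' @param m A filtered `ExpressionMatrix` (log2p1).
#' @param n_pcs Leading principal components to scan (default 6).
#' @param max_per_pc Cap per component (default 200).
#' @param p_cut Permutation p-value cutoff (default 1e-3).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @return Character vector of selected gene ids, with attribute `per_pc`
#'   (the per-component selections).
#' @export
select_informative_genes <- function(m, n_pcs = 6, max_per_pc = 200,
                                     p_cut = 1e-3, n_perm = 1000, seed = 1) {
  assert_log2p1(m)
  if (n_perm < 100) stop("n_perm must be >= 100")
  v <- m$values
  n <- nrow(v)
  if (n < n_pcs + 1) stop("fewer cells than n_pcs + 1")
  set.seed(as.integer(seed))
  pca <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  xc <- scale(v, center = TRUE, scale = FALSE)
  per_pc <- vector("list", n_pcs)
  for (k in seq_len(n_pcs)) {
    s <- pca$x[, k]
    obs <- abs(drop(crossprod(xc, s)))  # proportional to |loading|
    exceed <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      sp <- s[sample.int(n)]
      exceed <- exceed + (abs(drop(crossprod(xc, sp))) >= obs)
    }
    pval <- exceed / n_perm
    hits <- which(pval < p_cut)
    hits <- hits[order(obs[hits], decreasing = TRUE)]
    per_pc[[k]] <- colnames(v)[utils::head(hits, max_per_pc)]
  }
  out <- unique(unlist(per_pc))
  attr(out, "per_pc") <- per_pc
  out
}
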