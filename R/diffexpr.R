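#' Rank-sum z backend for two-group differential expression
#'
#' Continuity- and tie-corrected normal deviate of the Mann-Whitney U
#' statistic; positive z means higher expression in the first group. Used as
#' the default pluggable backend of [de_zscores()] (a substitute for heavier
#' single-cell error models: downstream logic consumes only z-scores).
#'
#' @param x,y Numeric expression values of the two groups.
#' @return A signed z-score (0 when the statistic is degenerate).
#' @export
ranksum_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tt <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  if (sigma2 <= 0) return(0)
  d <- U - mu
  if (abs(d) <= 0.5) return(0)
  (d - sign(d) * 0.5) / sqrt(sigma2)
}

#' Per-gene differential expression z-scores between two cell groups
#'
#' @param m An `ExpressionMatrix` (log2p1).
#' @param group_a,group_b Disjoint cell-id vectors (>= 3 cells each).
#'   Positive z = higher in `group_a`; for species comparisons the convention
#'   is human as `group_a` (positive z = higher in human).
#' @param backend Function `(x, y) -> z`; default [ranksum_z()].
#' @param comparison Label stored with the result (e.g. `"AP-vs-N.human"`).
#' @return A `DEResult` data.frame with `gene` and `z`, plus attributes
#'   `comparison`, `backend`, `n_a`, `n_b`. Genes all-zero in both groups get
#'   z = 0 (they are kept, flagged in column `tested`).
#' @export
de_zscores <- function(m, group_a, group_b, backend = ranksum_z,
                       comparison = "groupA-vs-groupB") {
  assert_log2p1(m)
  cells <- rownames(m$values)
  missing <- setdiff(c(group_a, group_b), cells)
  if (length(missing)) stop("unknown cell id: ", missing[1])
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3) stop("need >= 3 cells per group")
  A <- m$values[group_a, , drop = FALSE]
  B <- m$values[group_b, , drop = FALSE]
  tested <- colSums(A) + colSums(B) > 0
  z <- numeric(ncol(A))
  for (j in which(tested)) z[j] <- backend(A[, j], B[, j])
  out <- data.frame(gene = colnames(A), z = z, tested = tested,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  attr(out, "backend") <- deparse(substitute(backend))
  attr(out, "n_a") <- length(group_a)
  attr(out, "n_b") <- length(group_b)
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Call gene classes from cell-type and species z-score axes
#'
#' Cell-type specificity uses a 1-sd threshold on the cell-type z
#' distribution (AP-specific above mean + `k_type` sd, N-specific below
#' mean - `k_type` sd). Species differential expression uses the stricter
#' `k_species`-sd threshold on the species z distribution and is only called
#' for genes specific on the matching cell-type axis. Orientation: positive
#' species z = higher in human.
#'
#' @param z_celltype,z_species `DEResult`s over a shared gene list
#'   (cell-type axis: e.g. AP vs N; species axis: human vs chimpanzee).
#' @param k_type,k_species SD multipliers (defaults 1 and 2).
#' @return data.frame with `gene`, `z_type`, `z_species` and `class` in
#'   {AP-specific, N-specific, human-up-AP, human-up-N, chimp-up-AP,
#'   chimp-up-N, none}.
#' @export
specificity_calls <- function(z_celltype, z_species, k_type = 1, k_species = 2) {
  df <- merge(
    data.frame(gene = z_celltype$gene, z_type = z_celltype$z),
    data.frame(gene = z_species$gene, z_species = z_species$z),
    by = "gene"
  )
  if (nrow(df) == 0) stop("no shared genes between the two axes")
  sd_t <- stats::sd(df$z_type)
  sd_s <- stats::sd(df$z_species)
  if (is.na(sd_t) || sd_t == 0 || is.na(sd_s) || sd_s == 0) {
    warning("degenerate z-score distribution; no calls made")
    df$class <- "none"
    return(df)
  }
  mu_t <- mean(df$z_type)
  mu_s <- mean(df$z_species)
  ap <- df$z_type > mu_t + k_type * sd_t
  nn <- df$z_type < mu_t - k_type * sd_t
  hu <- df$z_species > mu_s + k_species * sd_s
  ch <- df$z_species < mu_s - k_species * sd_s
  cls <- rep("none", nrow(df))
  cls[ap] <- "AP-specific"
  cls[nn] <- "N-specific"
  cls[ap & hu] <- "human-up-AP"
  cls[ap & ch] <- "chimp-up-AP"
  cls[nn & hu] <- "human-up-N"
  cls[nn & ch] <- "chimp-up-N"
  df$class <- cls
  df
}

#' AP specificity score against non-neural cell lines
#'
#' Quantifies how restricted a gene's expression is to apical progenitors
#' relative to iPSCs and endothelial cells:
#' `score = mean_AP - max(mean_iPSC, mean_EC)` in log2 units (higher = more
#' AP-restricted).
#'
#' @param mean_ap,mean_ipsc,mean_ec Named numeric vectors of mean log2
#'   expression per gene in APs, iPSCs, and endothelial cells.
#' @return data.frame with `gene`, `score`, and `complete` (FALSE where the
#'   gene is missing from any source; such scores are `NA`, flagged rather
#'   than dropped).
#' @export
ap_specificity_score <- function(mean_ap, mean_ipsc, mean_ec) {
  genes <- unique(c(names(mean_ap), names(mean_ipsc), names(mean_ec)))
  if (length(genes) == 0) stop("no genes provided")
  complete <- genes %in% names(mean_ap) & genes %in% names(mean_ipsc) &
    genes %in% names(mean_ec)
  score <- rep(NA_real_, length(genes))
  g <- genes[complete]
  score[complete] <- mean_ap[g] - pmax(mean_ipsc[g], mean_ec[g])
  data.frame(gene = genes, score = score, complete = complete,
             stringsAsFactors = FALSE)
}

#' Partition cell-type-specific genes by evolutionary lineage
#'
#' Classifies genes called specific in human and/or chimpanzee against the
#' mouse call set: shared-with-mouse (in all three), human-chimp-ancestor
#' (human and chimp but not mouse), human-only and chimp-only. Proportions
#' are relative to the human-chimp union.
#'
#' @param calls_human,calls_chimp,calls_mouse Gene-id character vectors.
#' @return list with `counts`, `proportions` (both named by class) and
#'   `n_union`.
#' @export
lineage_partition <- function(calls_human, calls_chimp, calls_mouse) {
  hc <- union(calls_human, calls_chimp)
  if (length(hc) == 0) stop("empty human-chimp union")
  counts <- c(
    "shared-with-mouse" = length(intersect(intersect(calls_human, calls_chimp), calls_mouse)),
    "human-chimp-ancestor" = length(setdiff(intersect(calls_human, calls_chimp), calls_mouse)),
    "human-only" = length(setdiff(calls_human, union(calls_chimp, calls_mouse))),
    "chimp-only" = length(setdiff(calls_chimp, union(calls_human, calls_mouse)))
  )
  list(counts = counts, proportions = counts / length(hc), n_union = length(hc))
}
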