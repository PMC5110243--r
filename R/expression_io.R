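#' Construct an expression matrix
#'
#' Container for a cells x genes expression matrix with an explicit scale flag.
#' All downstream analysis operations require the `"log2p1"` scale
#' (log2(FPKM + 1)); matrices read from raw FPKM files must pass through
#' [log_transform()] first.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Row and
#'   column names are required and must be unique; values must be finite and
#'   non-negative.
#' @param scale Either `"log2p1"` (log2(FPKM+1), the analysis scale) or
#'   `"raw_fpkm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("log2p1", "raw_fpkm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x genes)")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must carry cell ids (rownames) and gene ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate cell id: ", rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene id: ", colnames(values)[duplicated(colnames(values))][1])
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

# internal guard used by every analysis operation
assert_log2p1 <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  if (m$scale != "log2p1") {
    stop("matrix must be on the log2(FPKM+1) scale; apply log_transform() first")
  }
  invisible(m)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of gene ids (first field is
#' the cell-id column label) and one row per cell. Parse errors (ragged rows,
#' duplicate ids, non-numeric or negative values) name the offending line.
#'
#' @param path File to read.
#' @param scale Scale flag to attach, see [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, scale = c("log2p1", "raw_fpkm")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("line 1: expected a header row and at least one cell row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  gene_ids <- header[-1]
  if (anyDuplicated(gene_ids)) {
    stop("line 1: duplicate gene id '", gene_ids[duplicated(gene_ids)][1], "'")
  }
  n_field <- length(header)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  cell_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(gene_ids))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != n_field) {
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, n_field, length(f)))
    }
    cell_ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric expression value", i + 1L))
    if (any(v < 0)) stop(sprintf("line %d: negative expression value", i + 1L))
    values[i, ] <- v
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell id '", cell_ids[duplicated(cell_ids)][1], "'")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  expression_matrix(values, scale)
}

#' Write an expression matrix to TSV
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output file.
#' @param digits Number of decimal places on write, or `NA` (default) for full
#'   double precision (round-trip exact via [read_expression_tsv()]).
#' @export
write_expression_tsv <- function(m, path, digits = NA) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  v <- m$values
  fmt <- if (is.na(digits)) {
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  } else {
    formatC(v, digits = digits, format = "f")
  }
  out <- cbind(cell_id = rownames(v), fmt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell_id", colnames(v)), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Sparse-triplet (MatrixMarket) expression I/O
#'
#' Writes/reads the matrix in MatrixMarket coordinate format (row, col, value
#' triplets) with sidecar id files `<path>.cells` and `<path>.genes`. Entries
#' absent from the triplet file are zeros.
#'
#' @param m An `ExpressionMatrix`.
#' @param path The `.mtx` file path.
#' @param scale Scale flag attached on read.
#' @return `read_expression_mtx()` returns an `ExpressionMatrix`.
#' @export
write_expression_mtx <- function(m, path) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  sm <- Matrix::Matrix(m$values, sparse = TRUE)
  Matrix::writeMM(sm, path)
  writeLines(rownames(m$values), paste0(path, ".cells"))
  writeLines(colnames(m$values), paste0(path, ".genes"))
  invisible(path)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(path, scale = c("log2p1", "raw_fpkm")) {
  scale <- match.arg(scale)
  v <- as.matrix(Matrix::readMM(path))
  cells <- readLines(paste0(path, ".cells"))
  genes <- readLines(paste0(path, ".genes"))
  if (nrow(v) != length(cells) || ncol(v) != length(genes)) {
    stop("triplet dimensions do not match sidecar id files")
  }
  dimnames(v) <- list(cells, genes)
  expression_matrix(v, scale)
}

#' Transform raw FPKM values to log2(FPKM + 1)
#'
#' The single normalization applied before any analysis: each value v becomes
#' log2(v + 1) and the scale flag is set to `"log2p1"`. Applying it to an
#' already-transformed matrix is an error (prevents double transforms).
#'
#' @param m An `ExpressionMatrix` on the `"raw_fpkm"` scale.
#' @return The transformed `ExpressionMatrix`.
#' @export
log_transform <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  if (m$scale == "log2p1") stop("matrix is already on the log2(FPKM+1) scale")
  expression_matrix(log2(m$values + 1), "log2p1")
}

#' Filter genes by expression breadth and variance
#'
#' Keeps genes expressed (value > 0) in strictly more than `min_cells` cells
#' and, by default, with non-zero variance across cells. Gene order is
#' preserved; the operation is idempotent.
#'
#' @param m An `ExpressionMatrix` on the log2(FPKM+1) scale.
#' @param min_cells Exclusive lower bound on the number of expressing cells
#'   (default 2: a gene seen in exactly two cells is removed).
#' @param require_variance Drop genes constant across all cells.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, min_cells = 2, require_variance = TRUE) {
  assert_log2p1(m)
  v <- m$values
  keep <- colSums(v > 0) > min_cells
  if (require_variance) {
    # population variance (denominator n); the test is qualitative (> 0)
    vars <- colMeans(v^2) - colMeans(v)^2
    keep <- keep & (vars > 0)
  }
  if (!any(keep)) warning("no genes survived filtering")
  expression_matrix(v[, keep, drop = FALSE], m$scale)
}

#' Per-cell metadata table
#'
#' @param cell_id Character vector of unique cell ids.
#' @param species,source,assigned_type,zone,cycle_phase Category columns;
#'   values must come from the closed sets documented below.
#' @return A `data.frame` with one row per cell.
#' @details Closed categories: species in human/chimpanzee/orangutan/mouse;
#'   source in organoid/fetal/iPSC/endothelial/B-cell; assigned_type in
#'   AP/BP/N/unassigned; zone in VZ/iSVZ/oSVZ/CP/unassigned; cycle_phase in
#'   G1/G2M/intermediate/unassigned.
#' @export
cell_meta <- function(cell_id, species, source = "organoid",
                      assigned_type = "unassigned", zone = "unassigned",
                      cycle_phase = "unassigned") {
  if (anyDuplicated(cell_id)) stop("duplicate cell id in metadata")
  chk <- function(x, allowed, what) {
    x <- rep_len(as.character(x), length(cell_id))
    bad <- setdiff(unique(x), allowed)
    if (length(bad)) stop(sprintf("invalid %s: %s", what, bad[1]))
    x
  }
  data.frame(
    cell_id = as.character(cell_id),
    species = chk(species, c("human", "chimpanzee", "orangutan", "mouse"), "species"),
    source = chk(source, c("organoid", "fetal", "iPSC", "endothelial", "B-cell"), "source"),
    assigned_type = chk(assigned_type, c("AP", "BP", "N", "unassigned"), "assigned_type"),
    zone = chk(zone, c("VZ", "iSVZ", "oSVZ", "CP", "unassigned"), "zone"),
    cycle_phase = chk(cycle_phase, c("G1", "G2M", "intermediate", "unassigned"), "cycle_phase"),
    stringsAsFactors = FALSE
  )
}
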