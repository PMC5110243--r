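# Independent oracles used to cross-check package computations. Each one is a
# deliberately naive implementation (enumeration, brute force, direct set
# arithmetic) kept separate from the code paths it audits.

# wrap a numeric matrix as a log2p1 ExpressionMatrix, inventing ids if absent
make_em <- function(values, scale = "log2p1") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, scale)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(N, n1)
  Us <- apply(cmb, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# naive per-position mask oracle: walk alignment columns, collect masked
# reference positions, expanding indel runs position by position
oracle_mask_positions <- function(aln, flank) {
  a <- strsplit(aln$seq_a, "")[[1]]
  b <- strsplit(aln$seq_b, "")[[1]]
  L <- sum(a != "-")
  masked <- rep(FALSE, L)
  pos <- -1L
  i <- 1
  while (i <= length(a)) {
    if (a[i] != "-" && b[i] != "-") {
      pos <- pos + 1L
      if (a[i] != b[i]) masked[pos + 1L] <- TRUE
      i <- i + 1
    } else if (b[i] == "-") {
      run_start <- pos + 1L
      while (i <= length(a) && b[i] == "-") {
        pos <- pos + 1L
        i <- i + 1
      }
      for (p in (run_start - flank):(pos + flank)) {
        if (p >= 0 && p < L) masked[p + 1L] <- TRUE
      }
    } else {  # gap in a: insertion point after `pos`
      while (i <= length(a) && a[i] == "-") i <- i + 1
      ins <- pos + 1L
      for (p in seq_len(2 * flank) - flank - 1L + ins) {
        if (p >= 0 && p < L) masked[p + 1L] <- TRUE
      }
    }
  }
  which(masked) - 1L
}

masked_positions <- function(mc) {
  iv <- mc$intervals
  if (nrow(iv) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(k) seq(iv[k, 1], iv[k, 2] - 1)))
}

# O(n^2) pairwise Pearson adjacency from first principles
oracle_adjacency <- function(values, tau) {
  n <- nrow(values)
  adj <- matrix(FALSE, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- values[i, ]
      xj <- values[j, ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      adj[i, j] <- adj[j, i] <- (num / den) > tau
    }
  }
  adj
}

# signature score by explicit set arithmetic
oracle_set_score <- function(cell, sig_genes, threshold) {
  expressed <- names(cell)[cell > threshold]
  if (length(expressed) == 0) return(NA_real_)
  length(intersect(expressed, sig_genes)) / length(expressed)
}

# Spearman rho by explicit rank arithmetic (no cor())
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# minimum spanning tree by exhaustive Pruefer-sequence enumeration (n <= 6)
# returns the edge list of the minimum-weight spanning tree
oracle_mst_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 6)
  pruefer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (v in seq) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, nrow = n - 1, ncol = 2)
    ptr <- seq
    k <- 1
    while (length(ptr) > 0) {
      leaf <- min(which(degree == 1L))
      v <- ptr[1]
      edges[k, ] <- c(leaf, v)
      k <- k + 1
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
      ptr <- ptr[-1]
    }
    last <- which(degree == 1L)
    edges[k, ] <- last
    edges
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- NULL
  best_w <- Inf
  for (row in seq_len(nrow(grid))) {
    ed <- pruefer_to_edges(as.integer(grid[row, ]))
    w <- sum(d[ed])
    if (w < best_w - 1e-12) {
      best_w <- w
      best <- ed
    }
  }
  list(edges = best, weight = best_w)
}

# longest path (weighted diameter) of a tree given its edges, by enumerating
# all vertex pairs and walking unique tree paths
oracle_tree_diameter <- function(edges, d) {
  n <- max(edges)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]
    j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  path_between <- function(from, to) {
    stack <- list(list(v = from, path = from))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (top$v == to) return(top$path)
      for (w in adj[[top$v]]) {
        if (!(w %in% top$path)) stack[[length(stack) + 1]] <- list(v = w, path = c(top$path, w))
      }
    }
    NULL
  }
  best <- NULL
  best_w <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- path_between(i, j)
      w <- sum(d[cbind(p[-length(p)], p[-1])])
      if (w > best_w + 1e-12) {
        best_w <- w
        best <- p
      }
    }
  }
  list(path = best, weight = best_w)
}

# stated-world mitosis groups used across tests (human vs chimp organoid APs,
# +5 min prometaphase+metaphase in human, located in metaphase)
mitosis_groups_2sp <- function(n = 60, sd = 2) {
  h <- c(prophase = 5.5, prometaphase = 5.5, metaphase = 9.9,
         anaphase = 2.2, telophase = 5.5)
  c2 <- h
  c2["metaphase"] <- 4.9
  list(list(label = "human", n = n, means = h, sds = sd),
       list(label = "chimp", n = n, means = c2, sds = sd))
}
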