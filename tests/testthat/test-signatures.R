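test_that("pc1_signatures recovers a planted dominant gradient", {
  # rank-1 matrix: 10 cells on a gradient, 5 genes loading up, 5 down;
  # oracle: with a single dominant direction, PC1 is that direction, so the
  # up-genes must head the NSPC list (n_top = 5)
  s <- seq(-2, 2, length.out = 10)
  up <- outer(s, rep(1, 5))
  down <- outer(-s, rep(1, 5))
  v <- cbind(up, down) + 5
  set.seed(4)
  v <- v + matrix(rnorm(100, 0, 0.01), 10, 10)
  dimnames(v) <- list(sprintf("c%02d", 1:10), c(paste0("up", 1:5), paste0("dn", 1:5)))
  m <- expression_matrix(v, "log2p1")
  sig <- pc1_signatures(m, n_top = 5, orient_genes = paste0("up", 1:5))
  expect_setequal(sig$nspc_genes, paste0("up", 1:5))
  expect_setequal(sig$neuron_genes, paste0("dn", 1:5))

  # oracle cross-check: PC1 scores match the leading eigenvector of the
  # covariance computed by direct eigendecomposition (up to sign/scale)
  xc <- scale(v, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(v) - 1))$vectors[, 1]
  expect_gt(abs(cor(sig$pc1_cell_scores, drop(xc %*% ev))), 0.999999)

  # orientation rule makes the lists invariant to a flipped gradient
  v2 <- cbind(outer(-s, rep(1, 5)), outer(s, rep(1, 5))) + 5
  dimnames(v2) <- dimnames(v)
  sig2 <- pc1_signatures(expression_matrix(v2, "log2p1"), n_top = 5,
                         orient_genes = paste0("up", 1:5))
  expect_setequal(sig2$nspc_genes, paste0("up", 1:5))

  const <- make_em(matrix(5, 6, 10))
  expect_error(pc1_signatures(const, n_top = 3), "constant")
  expect_error(pc1_signatures(m, n_top = 11), "n_top exceeds")
})

test_that("signature scores are above-threshold set fractions", {
  sig <- structure(list(nspc_genes = paste0("n", 1:5),
                        neuron_genes = paste0("m", 1:5)), class = "SignatureSet")
  cell <- setNames(rep(0, 20), c(paste0("n", 1:5), paste0("m", 1:5), paste0("x", 1:10)))
  cell[c("n1", "n2", "n3")] <- 6          # 3 NSPC genes above threshold
  cell[c("x1", "x2", "x3", "x4", "x5", "x6", "m1")] <- 7  # 7 more above
  sc <- signature_score(cell, sig, threshold = 5)
  expect_equal(sc$nspc_score, 0.3)        # 3 of 10
  expect_equal(sc$neuron_score, 0.1)

  none <- signature_score(setNames(rep(1, 5), paste0("n", 1:5)), sig, threshold = 5)
  expect_true(is.na(none$nspc_score))
  expect_identical(none$n_expressed, 0L)

  # random cell agrees with the independent set-arithmetic oracle
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  big <- structure(list(nspc_genes = sample(genes, 40),
                        neuron_genes = setdiff(genes, sample(genes, 150))[1:20]),
                   class = "SignatureSet")
  for (i in 1:10) {
    cell <- setNames(runif(200, 0, 10), genes)
    sc <- signature_score(cell, big, threshold = 5)
    expect_equal(sc$nspc_score, oracle_set_score(cell, big$nspc_genes, 5))
    expect_equal(sc$neuron_score, oracle_set_score(cell, big$neuron_genes, 5))
    # invariance: perturbing below-threshold values never changes the score
    cell2 <- cell
    cell2[cell2 < 5] <- cell2[cell2 < 5] / 2
    expect_equal(signature_score(cell2, big, 5)$nspc_score, sc$nspc_score)
  }
})

test_that("signature scoring recovers the progenitor-to-neuron axis", {
  sim <- gen_expression(sim_config(seed = 6))
  fm <- filter_genes(sim$matrix)
  sig <- pc1_signatures(fm, n_top = 50, orient_genes = sim$truth$marker_genes$AP)
  sc <- signature_scores(fm, sig, threshold = 5)
  ty <- sim$truth$true_type[sc$cell_id]
  expect_gt(mean(sc$nspc_score[ty == "AP"], na.rm = TRUE),
            mean(sc$nspc_score[ty == "N"], na.rm = TRUE))
  expect_gt(mean(sc$neuron_score[ty == "N"], na.rm = TRUE),
            mean(sc$neuron_score[ty == "AP"], na.rm = TRUE))
})

test_that("informative-gene selection finds planted programs and caps output", {
  set.seed(31)
  n <- 30
  v <- matrix(runif(n * 100, 0, 4), n, 100)
  prog <- rnorm(n)
  v[, 1:20] <- v[, 1:20] + outer(prog, rep(3, 20))  # strong 20-gene program
  m <- make_em(pmax(v, 0))
  got <- select_informative_genes(m, n_pcs = 2, n_perm = 200, seed = 1)
  expect_true(all(colnames(m$values)[1:20] %in% attr(got, "per_pc")[[1]]))

  capped <- select_informative_genes(m, n_pcs = 4, max_per_pc = 1,
                                     n_perm = 100, seed = 1)
  expect_lte(length(capped), 4)

  expect_error(select_informative_genes(make_em(matrix(runif(50), 5, 10)),
                                        n_pcs = 6, n_perm = 100),
               "fewer cells")
})

test_that("selection rate on pure noise is bounded near the permutation cutoff", {
  # The fixed-PC permutation test (shuffle a gene's cells, recompute its
  # loading against the unchanged PC scores) is anti-conservative for the
  # leading components: PC1 is chosen to maximize variance, so observed
  # loadings are inflated relative to the permutation null (the selection
  # bias the jackstraw literature documents). On pure noise the selected
  # fraction therefore sits between p_cut and a few multiples of it.
  set.seed(77)
  v <- matrix(rnorm(40 * 400, 5, 1), 40, 400)
  m <- make_em(pmax(v, 0))
  got <- select_informative_genes(m, n_pcs = 6, p_cut = 0.05, n_perm = 200, seed = 3)
  per_pc <- attr(got, "per_pc")
  n_pc1 <- length(per_pc[[1]])
  expect_gt(n_pc1, 5)          # not conservative: at least ~p_cut * n_genes
  expect_lt(n_pc1, 0.05 * 400 * 5)  # inflation stays within a small factor
  # the strict default cutoff still prunes almost everything
  strict <- select_informative_genes(m, n_pcs = 6, p_cut = 1e-3, n_perm = 500, seed = 3)
  expect_lt(length(strict), 0.025 * 2400)
})
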