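toy_zone_ref <- function(genes = 12, seed = 5) {
  set.seed(seed)
  profiles <- matrix(runif(4 * genes, 0, 8), 4,
                     dimnames = list(c("VZ", "iSVZ", "oSVZ", "CP"),
                                     sprintf("g%02d", seq_len(genes))))
  zone_reference(profiles)
}

test_that("zone assignment follows the maximum Spearman correlation", {
  ref <- toy_zone_ref()
  vz <- ref$profiles["VZ", ]
  v <- rbind(match_vz = vz,                     # identical to VZ
             rev_vz = max(vz) - vz + min(vz))   # rank-reversed VZ
  v <- pmax(v, 0)
  m <- make_em(v)
  za <- zone_assign(m, ref)
  expect_identical(za$zone[1], "VZ")
  expect_equal(za$rho_VZ[1], 1)
  expect_false(za$zone[2] == "VZ")
  expect_equal(za$rho_VZ[2], -1)
})

test_that("zone correlations match exhaustive rank arithmetic on a toy cell", {
  ref <- toy_zone_ref(genes = 12, seed = 9)
  set.seed(10)
  cellv <- matrix(runif(12, 0, 8), 1, dimnames = list("q", colnames(ref$profiles)))
  za <- zone_assign(make_em(cellv), ref)
  for (z in c("VZ", "iSVZ", "oSVZ", "CP")) {
    expect_equal(za[[paste0("rho_", z)]],
                 oracle_spearman(cellv[1, ], ref$profiles[z, ]))
  }
  # the scaled values are the z-scores of the raw correlations
  raw <- unlist(za[paste0("rho_", c("VZ", "iSVZ", "oSVZ", "CP"))])
  expect_equal(unname(unlist(za[paste0("z_", c("VZ", "iSVZ", "oSVZ", "CP"))])),
               unname((raw - mean(raw)) / sd(raw)))
})

test_that("zone assignment is invariant to strictly monotone per-cell maps", {
  ref <- toy_zone_ref(genes = 20, seed = 2)
  set.seed(3)
  v <- matrix(runif(5 * 20, 0, 8), 5, dimnames = list(sprintf("c%d", 1:5),
                                                      colnames(ref$profiles)))
  base <- zone_assign(make_em(v), ref)
  maps <- list(function(x) x^3, function(x) exp(x) - 1, function(x) 2 * x + 1,
               function(x) log1p(x), function(x) x^1.7)
  v2 <- v
  for (i in 1:5) v2[i, ] <- maps[[i]](v[i, ])
  mapped <- zone_assign(make_em(v2), ref)
  expect_identical(mapped$zone, base$zone)
  for (z in c("VZ", "iSVZ", "oSVZ", "CP")) {
    expect_equal(mapped[[paste0("rho_", z)]], base[[paste0("rho_", z)]])
  }
})

test_that("constant cells are flagged unassigned in zone assignment", {
  ref <- toy_zone_ref(genes = 12)
  v <- rbind(flat = rep(3, 12), ok = ref$profiles["CP", ])
  colnames(v) <- colnames(ref$profiles)
  za <- zone_assign(make_em(v), ref)
  expect_identical(za$zone, c("unassigned", "CP"))
})

test_that("cell types come from the maximally correlated reference cell", {
  set.seed(14)
  genes <- sprintf("g%02d", 1:30)
  refv <- matrix(runif(6 * 30, 0, 8), 6, dimnames = list(
    c("r1", "r2", "r3", "r4", "r5", "r6"), genes))
  ref <- fetal_reference(make_em(refv), setNames(
    c("AP1", "AP2", "BP1", "BP2", "N1", "N3"), rownames(refv)))
  qry <- make_em(refv["r1", , drop = FALSE] + 0)
  rownames(qry$values) <- "query"
  qry <- expression_matrix(qry$values, "log2p1")
  ta <- celltype_assign(qry, ref)
  expect_identical(ta$assigned_type, "AP")
  expect_identical(ta$best_ref, "r1")

  # Pearson property: per-cell affine transforms do not change assignments
  qa <- expression_matrix(qry$values * 3 + 2, "log2p1")
  expect_identical(celltype_assign(qa, ref)$assigned_type, "AP")

  other <- make_em(matrix(1:4, 2, 2, dimnames = list(c("x1", "x2"),
                                                     c("zz1", "zz2"))))
  expect_error(celltype_assign(other, ref), "empty gene intersection")

  # argmax ties break toward the lowest reference cell id, with a warning
  refv2 <- rbind(refv["r1", , drop = FALSE], refv["r1", , drop = FALSE])
  rownames(refv2) <- c("zz", "aa")
  ref2 <- fetal_reference(make_em(rbind(refv2, refv[3:5, ])), setNames(
    c("N1", "AP1", "BP1", "BP2", "N1"), c("zz", "aa", "r3", "r4", "r5")))
  expect_warning(ta2 <- celltype_assign(qry, ref2), "tied")
  expect_identical(ta2$best_ref, "aa")
  expect_identical(ta2$assigned_type, "AP")
})

test_that("cell-type recovery on simulated data reaches 90%", {
  ref_sim <- gen_expression(sim_config(seed = 101))
  qry_sim <- gen_expression(sim_config(type_effect = 2.0, seed = 42))
  ref <- fetal_reference(ref_sim$matrix, ref_sim$truth$true_type)
  ta <- suppressMessages(celltype_assign(qry_sim$matrix, ref))
  acc <- mean(ta$assigned_type == qry_sim$truth$true_type[ta$cell_id])
  expect_gte(acc, 0.9)
})

test_that("cycle assignment separates constructed G2M and G1 blocks", {
  # phase separation rides on the panel's expression profile: G2M cells share
  # base + amplitude, G1 cells the base profile alone
  genes <- paste0("cc", 1:8)
  set.seed(6)
  base <- runif(8, 1, 4)
  amp <- runif(8, 0, 6)
  hi <- t(replicate(5, base + amp + rnorm(8, 0, 0.1)))
  lo <- t(replicate(5, base + rnorm(8, 0, 0.1)))
  mid <- t(replicate(2, base + amp / 2 + rnorm(8, 0, 0.1)))
  v <- rbind(hi, lo, mid)
  dimnames(v) <- list(c(paste0("hi", 1:5), paste0("lo", 1:5), "mid1", "mid2"), genes)
  ca <- cycle_assign(make_em(pmax(v, 0)), genes)
  expect_true(all(ca$phase[1:5] == "G2M"))
  expect_true(all(ca$phase[6:10] == "G1"))

  flat <- make_em(matrix(3, 6, 8, dimnames = list(paste0("c", 1:6), genes)))
  expect_true(all(cycle_assign(flat, genes)$phase == "intermediate"))

  expect_error(cycle_assign(make_em(matrix(runif(40), 5, 8)), genes), ">= 6 cells")
  expect_error(cycle_assign(make_em(matrix(runif(60), 6, 10)), paste0("cc", 1:4)),
               "g2m genes")
})

test_that("cycle-phase recovery on simulated progenitors reaches 85%", {
  csim <- gen_expression(sim_config(cycle_effect = 2.0, seed = 42))
  prog <- names(csim$truth$true_type)[csim$truth$true_type %in% c("AP", "BP")]
  sub <- expression_matrix(csim$matrix$values[prog, , drop = FALSE], "log2p1")
  ca <- cycle_assign(sub, csim$truth$cycle_genes)
  ni <- ca$phase != "intermediate"
  acc <- mean(ca$phase[ni] == csim$truth$true_phase[ca$cell_id][ni])
  expect_gte(acc, 0.85)
})
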