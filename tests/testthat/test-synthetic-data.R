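test_that("gen_expression is seeded-deterministic and validates its config", {
  cfg <- sim_config(n_cells_per_species = 50, n_genes = 200, seed = 7)
  a <- gen_expression(cfg)
  b <- gen_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  expect_error(sim_config(n_cells_per_species = 1), "invalid config")
  expect_error(sim_config(n_genes = 10), "invalid config")
  expect_error(sim_config(type_effect = -1), "invalid config")
  expect_error(sim_config(dropout = 1.5), "invalid config")
  expect_error(sim_config(n_genes = 20, n_signature = 40), "invalid config")
})

test_that("degenerate config yields a matrix constant across cells", {
  sim <- gen_expression(sim_config(type_effect = 0, cycle_effect = 0,
                                   species_effect = 0, dropout = 0,
                                   noise_sd = 0, seed = 3))
  vars <- apply(sim$matrix$values, 2, var)
  expect_true(all(vars == 0))
})

test_that("type program separates signature genes between AP and N cells", {
  # recompute the means directly from the emitted matrix and truth labels
  sim <- gen_expression(sim_config(type_effect = 2.0, seed = 1))
  v <- sim$matrix$values
  ap <- names(sim$truth$true_type)[sim$truth$true_type == "AP"]
  nn <- names(sim$truth$true_type)[sim$truth$true_type == "N"]
  nspc <- sim$truth$signature_genes$nspc
  expect_gte(mean(v[ap, nspc]) - mean(v[nn, nspc]), 1.0)
})

test_that("simulation truth respects its structural invariants", {
  sim <- gen_expression(sim_config(seed = 11))
  tr <- sim$truth
  expect_length(intersect(tr$signature_genes$nspc, tr$signature_genes$neuron), 0)
  expect_true(all(names(tr$species_shift_genes) %in% colnames(sim$matrix$values)))
  pt_by_type <- tapply(tr$pseudotime, tr$true_type, mean)
  expect_lt(pt_by_type[["AP"]], pt_by_type[["BP"]])
  expect_lt(pt_by_type[["BP"]], pt_by_type[["N"]])
  expect_true(all(sim$matrix$values >= 0))
  # species shift is present in the stated cell type
  hu_ap <- names(tr$species)[tr$species == "human" & tr$true_type == "AP"]
  ch_ap <- names(tr$species)[tr$species == "chimpanzee" & tr$true_type == "AP"]
  shift <- names(tr$species_shift_genes)
  d <- colMeans(sim$matrix$values[hu_ap, shift]) - colMeans(sim$matrix$values[ch_ap, shift])
  expect_true(all(abs(d - 2) < 1))
})

test_that("shuffling species labels destroys species-shift detectability", {
  sim <- gen_expression(sim_config(seed = 5))
  tr <- sim$truth
  set.seed(99)
  perm_species <- setNames(sample(tr$species), names(tr$species))
  ap <- names(tr$true_type)[tr$true_type == "AP"]
  hu <- intersect(ap, names(perm_species)[perm_species == "human"])
  ch <- intersect(ap, names(perm_species)[perm_species == "chimpanzee"])
  shift <- names(tr$species_shift_genes)
  d <- colMeans(sim$matrix$values[hu, shift]) - colMeans(sim$matrix$values[ch, shift])
  expect_lt(mean(abs(d)), 1)  # below half the configured effect of 2
})

test_that("zone reference profiles are pseudotime-quartile means", {
  sim <- gen_expression(sim_config(seed = 2))
  zr <- gen_zone_reference(sim$truth, sim$matrix)
  pt <- sim$truth$pseudotime[rownames(sim$matrix$values)]
  q <- quantile(pt, 0:4 / 4, names = FALSE)
  vz_cells <- names(pt)[pt >= q[1] & pt <= q[2]]
  brute <- colMeans(sim$matrix$values[vz_cells, , drop = FALSE])
  expect_equal(unname(zr$profiles["VZ", ]), unname(brute))

  # degenerate pseudotime: all four profiles identical
  tr0 <- sim$truth
  tr0$pseudotime[] <- 0
  zr0 <- gen_zone_reference(tr0, sim$matrix)
  expect_equal(zr0$profiles["VZ", ], zr0$profiles["CP", ])
  expect_equal(zr0$profiles["iSVZ", ], zr0$profiles["oSVZ", ])

  # error cases
  empty <- expression_matrix(matrix(0, 0, 3, dimnames = list(NULL, c("a", "b", "c"))),
                             "log2p1")
  expect_error(gen_zone_reference(sim$truth, empty), "insufficient|empty")
  small <- make_em(matrix(runif(9), 3, 3))
  tr_small <- list(pseudotime = setNames(runif(3), rownames(small$values)))
  expect_error(gen_zone_reference(tr_small, small), "insufficient")
})

test_that("mitosis tracks sit on the frame grid with truncated durations", {
  grp <- mitosis_groups_2sp(n = 40)
  tr <- gen_mitosis_tracks(grp, frame_interval = 1.1, seed = 4)
  tr2 <- gen_mitosis_tracks(grp, frame_interval = 1.1, seed = 4)
  expect_identical(tr, tr2)

  ev <- as.matrix(tr[, grep("^t_", names(tr))])
  expect_true(all(abs(ev / 1.1 - round(ev / 1.1)) < 1e-9))
  d <- phase_durations(tr)
  expect_true(all(as.matrix(d[, c("prophase", "prometaphase", "metaphase",
                                  "anaphase", "telophase")]) >= 1.1 - 1e-9))
  expect_identical(unique(tr$group), c("human", "chimp"))

  # sd = 0 with a vanishing frame interval recovers the configured means
  tr0 <- gen_mitosis_tracks(list(list(label = "x", n = 5,
                                      means = c(prophase = 5.5, prometaphase = 4.4,
                                                metaphase = 6.6, anaphase = 2.2,
                                                telophase = 3.3), sds = 0)),
                            frame_interval = 1e-6, seed = 1)
  d0 <- phase_durations(tr0)
  expect_equal(d0$prophase, rep(5.5, 5), tolerance = 1e-5)
  expect_equal(d0$metaphase, rep(6.6, 5), tolerance = 1e-5)

  expect_error(gen_mitosis_tracks(list(list(label = "x", n = 3,
                                            means = c(prophase = 1, prometaphase = 1,
                                                      metaphase = 1, anaphase = 1,
                                                      telophase = 1), sds = -1))),
               "invalid config")
})

test_that("configured +5 min prometaphase+metaphase shift is realized", {
  # direct Monte-Carlo check: sample mean difference within 3 SEM of 5.0
  tr <- gen_mitosis_tracks(mitosis_groups_2sp(n = 200), seed = 12)
  d <- phase_durations(tr)
  m <- tapply(d$prometa_meta, d$group, mean)
  s <- tapply(d$prometa_meta, d$group, function(x) sd(x) / sqrt(length(x)))
  sem <- sqrt(sum(s^2))
  expect_lt(abs((m[["human"]] - m[["chimp"]]) - 5.0), 3 * sem)
})

test_that("orientation tracks follow the angle model", {
  # jitter 0, drift 0: every sample equals the base angle
  ot <- gen_orientation_tracks(3, base_angle = 72, drift_per_min = 0,
                               jitter_sd = 0, seed = 1)
  expect_true(all(vapply(ot, function(t) all(t$samples$angle_deg == 72), TRUE)))
  expect_true(all(vapply(ot, function(t) {
    max(t$samples$time_min) >= t$t_anaphase_onset + 2.2
  }, TRUE)))

  ot2 <- gen_orientation_tracks(3, base_angle = 72, jitter_sd = 0, seed = 1)
  expect_identical(ot, ot2)

  # Monte-Carlo: jitter sd 5 -> empirical angle sd within [3, 7] degrees
  # (base 45 keeps the [0,90] clip inactive)
  big <- gen_orientation_tracks(500, base_angle = 45, jitter_sd = 5, seed = 2)
  angles <- unlist(lapply(big, function(t) t$samples$angle_deg))
  expect_gt(sd(angles), 3)
  expect_lt(sd(angles), 7)
})

test_that("labeling curves follow the linear-rise-to-plateau model", {
  p <- cell_cycle_params(46.5, 17.5, 0.9)
  expect_equal(gen_labeling_curve(p, times = 0)$labeling_index, 0.9 * 17.5 / 46.5)
  expect_equal(gen_labeling_curve(p, times = c(29, 35, 48))$labeling_index,
               rep(0.9, 3))  # t >= Tc - Ts
  expect_equal(gen_labeling_curve(p, times = 6)$labeling_index,
               0.9 * (6 + 17.5) / 46.5)  # = 0.454839
  expect_error(cell_cycle_params(tc_h = 10, ts_h = 12, gf = 0.9), "invalid params")

  # property: noiseless curve non-decreasing and bounded by GF
  set.seed(8)
  for (i in 1:20) {
    tc <- runif(1, 10, 60)
    ts <- runif(1, 1, tc - 1)
    gf <- runif(1, 0.2, 1)
    li <- gen_labeling_curve(cell_cycle_params(tc, ts, gf),
                             times = sort(runif(10, 0, 80)))$labeling_index
    expect_true(all(diff(li) >= -1e-12))
    expect_true(all(li <= gf + 1e-12))
  }
})

test_that("toy alignments carry exactly the configured events", {
  a0 <- gen_toy_alignment(30, n_snps = 0, seed = 1)
  expect_identical(a0$seq_a, a0$seq_b)
  expect_false(grepl("-", a0$seq_a, fixed = TRUE))

  a1 <- gen_toy_alignment(30, n_snps = 1, seed = 2)
  ca <- strsplit(a1$seq_a, "")[[1]]
  cb <- strsplit(a1$seq_b, "")[[1]]
  expect_identical(sum(ca != cb), 1L)
  expect_identical(which(ca != cb) - 1L, a1$truth$snps)

  expect_identical(gen_toy_alignment(50, 5, seed = 9),
                   gen_toy_alignment(50, 5, seed = 9))

  expect_error(
    gen_toy_alignment(30, indels = list(list(position = 5, length = 3, which = "b"),
                                        list(position = 6, length = 2, which = "b"))),
    "overlap")
})
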