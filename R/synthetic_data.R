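#' Simulation configuration
#'
#' Describes the synthetic two-species organoid world: an AP -> BP -> N
#' expression continuum (pseudotime in \[0,1\], types by tercile) carrying
#' additive log-scale gene programs, a G1/G2M cell-cycle program, a small set
#' of genes shifted in human APs, Gaussian noise, and Bernoulli dropout.
#'
#' @param n_cells_per_species Cells simulated per species (human, chimpanzee).
#' @param n_genes Total genes; must accommodate the gene blocks below.
#' @param type_effect,cycle_effect,species_effect Program amplitudes in log2
#'   units (all must be >= 0).
#' @param dropout Per-entry Bernoulli dropout probability in \[0,1\].
#' @param noise_sd Gaussian noise standard deviation (log2 units, >= 0).
#' @param n_signature Genes per differentiation signature (NSPC-like and
#'   neuron-like gradients).
#' @param n_cycle_genes Genes in the G2M program.
#' @param n_shift_genes Genes carrying the AP program plus a human-AP shift of
#'   `species_effect` log2 units.
#' @param n_type_markers Discrete marker genes per cell type (AP, BP, N).
#' @param n_housekeeping Constant highly expressed genes (score denominators).
#' @param p_g2m_progenitor,p_g2m_neuron Probability a progenitor/neuron is in
#'   G2M.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_cells_per_species = 100, n_genes = 200,
                       type_effect = 2, cycle_effect = 1, species_effect = 2,
                       dropout = 0.02, noise_sd = 0.25,
                       n_signature = 40, n_cycle_genes = 20, n_shift_genes = 10,
                       n_type_markers = 10, n_housekeeping = 20,
                       p_g2m_progenitor = 0.3, p_g2m_neuron = 0.05,
                       seed = 1) {
  cfg <- list(
    n_cells_per_species = as.integer(n_cells_per_species),
    n_genes = as.integer(n_genes),
    type_effect = type_effect, cycle_effect = cycle_effect,
    species_effect = species_effect,
    dropout = dropout, noise_sd = noise_sd,
    n_signature = as.integer(n_signature),
    n_cycle_genes = as.integer(n_cycle_genes),
    n_shift_genes = as.integer(n_shift_genes),
    n_type_markers = as.integer(n_type_markers),
    n_housekeeping = as.integer(n_housekeeping),
    p_g2m_progenitor = p_g2m_progenitor, p_g2m_neuron = p_g2m_neuron,
    seed = as.integer(seed)
  )
  if (cfg$n_cells_per_species < 3) stop("invalid config: need >= 3 cells per species")
  if (cfg$n_genes < 20) stop("invalid config: need >= 20 genes")
  if (any(c(cfg$type_effect, cfg$cycle_effect, cfg$species_effect) < 0)) {
    stop("invalid config: effect sizes must be >= 0")
  }
  if (cfg$dropout < 0 || cfg$dropout > 1) stop("invalid config: dropout must be in [0,1]")
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  used <- 2 * cfg$n_signature + cfg$n_cycle_genes + cfg$n_shift_genes +
    3 * cfg$n_type_markers + cfg$n_housekeeping
  if (used > cfg$n_genes) {
    stop("invalid config: gene blocks (", used, ") exceed n_genes (", cfg$n_genes, ")")
  }
  structure(cfg, class = "SimConfig")
}

#' Generate a synthetic two-species expression matrix with ground truth
#'
#' Additive log-scale model per cell i and gene g: a block baseline plus the
#' type, cycle and species programs, Gaussian noise, hard-zero dropout, and a
#' clip at 0 so values live on the log2(FPKM+1) scale. Pseudotime is uniform
#' on \[0,1\]; cell types are pseudotime terciles (AP < 1/3 <= BP < 2/3 <= N),
#' so mean pseudotime increases AP -> BP -> N by construction.
#'
#' Gene blocks (in matrix order): NSPC-signature genes (baseline 4, amplitude
#' `type_effect * (1 - pseudotime)`), neuron-signature genes (mirror image),
#' G2M genes (baseline 2 + `cycle_effect` in G2M cells), species-shift genes
#' (the NSPC gradient plus `species_effect` in human APs), discrete AP/BP/N
#' marker blocks (baseline 3 + `type_effect` in the matching type),
#' housekeeping genes (constant 6), and low background (2).
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (an `ExpressionMatrix`, log2p1 scale),
#'   `meta` (a [cell_meta()] data.frame) and `truth` (a `SimTruth` list with
#'   `pseudotime`, `true_type`, `true_phase`, `species`,
#'   `species_shift_genes` (named per-gene log2 effects), `signature_genes`
#'   (disjoint `nspc`/`neuron` sets), `cycle_genes`, `marker_genes`).
#' @export
gen_expression <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ncs <- config$n_cells_per_species
  n <- 2L * ncs
  g <- config$n_genes
  species <- rep(c("human", "chimpanzee"), each = ncs)
  cell_id <- paste0(species, "_", sprintf("%03d", c(seq_len(ncs), seq_len(ncs))))
  pt <- stats::runif(n)
  true_type <- as.character(cut(pt, c(0, 1 / 3, 2 / 3, 1),
                                labels = c("AP", "BP", "N"), include.lowest = TRUE))
  p_g2m <- ifelse(true_type == "N", config$p_g2m_neuron, config$p_g2m_progenitor)
  true_phase <- ifelse(stats::runif(n) < p_g2m, "G2M", "G1")

  gene_id <- sprintf("g%04d", seq_len(g))
  idx <- 0L
  take <- function(k) {
    out <- gene_id[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  nspc_genes <- take(config$n_signature)
  neuron_genes <- take(config$n_signature)
  cycle_genes <- take(config$n_cycle_genes)
  shift_genes <- take(config$n_shift_genes)
  ap_markers <- take(config$n_type_markers)
  bp_markers <- take(config$n_type_markers)
  n_markers <- take(config$n_type_markers)
  hk_genes <- take(config$n_housekeeping)
  # remaining genes are low-expression background (baseline 2)

  mu <- matrix(2, nrow = n, ncol = g, dimnames = list(cell_id, gene_id))
  mu[, nspc_genes] <- 4 + config$type_effect * (1 - pt)
  mu[, neuron_genes] <- 4 + config$type_effect * pt
  # heterogeneous per-gene baselines/amplitudes: correlation-based phase
  # clustering keys on the panel's expression profile, which is flat only in
  # an unrealistically uniform panel
  cyc_base <- stats::runif(length(cycle_genes), 0, 2)
  cyc_amp <- config$cycle_effect * stats::runif(length(cycle_genes), 0.25, 1.75)
  mu[, cycle_genes] <- matrix(cyc_base, n, length(cycle_genes), byrow = TRUE) +
    outer(as.numeric(true_phase == "G2M"), cyc_amp)
  mu[, shift_genes] <- 4 + config$type_effect * (1 - pt) +
    config$species_effect * (species == "human" & true_type == "AP")
  mu[, ap_markers] <- 3 + config$type_effect * (true_type == "AP")
  mu[, bp_markers] <- 3 + config$type_effect * (true_type == "BP")
  mu[, n_markers] <- 3 + config$type_effect * (true_type == "N")
  mu[, hk_genes] <- 6

  vals <- mu + matrix(stats::rnorm(n * g, 0, config$noise_sd), n, g)
  if (config$dropout > 0) {
    vals[matrix(stats::runif(n * g) < config$dropout, n, g)] <- 0
  }
  vals <- pmax(vals, 0)

  truth <- structure(list(
    pseudotime = stats::setNames(pt, cell_id),
    true_type = stats::setNames(true_type, cell_id),
    true_phase = stats::setNames(true_phase, cell_id),
    species = stats::setNames(species, cell_id),
    species_shift_genes = stats::setNames(
      rep(config$species_effect, length(shift_genes)), shift_genes),
    signature_genes = list(nspc = nspc_genes, neuron = neuron_genes),
    cycle_genes = cycle_genes,
    marker_genes = list(AP = ap_markers, BP = bp_markers, N = n_markers),
    housekeeping_genes = hk_genes
  ), class = "SimTruth")

  list(
    matrix = expression_matrix(vals, "log2p1"),
    meta = cell_meta(cell_id, species = species, source = "organoid"),
    truth = truth
  )
}

#' Build a four-zone bulk reference from simulated cells
#'
#' Emulates microdissected-zone bulk profiles: cells are binned by pseudotime
#' quartile and each zone profile is the mean expression of its bin
#' (VZ = earliest quartile ... CP = latest). Bin edges are the pseudotime
#' quartiles; cells sitting exactly on an edge contribute to both flanking
#' zones, and degenerate pseudotime (all equal) yields four identical
#' profiles.
#'
#' @param truth A `SimTruth` from [gen_expression()].
#' @param m The matching `ExpressionMatrix`.
#' @return A `ZoneReference` (see [zone_reference()]).
#' @export
gen_zone_reference <- function(truth, m) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  if (ncol(m$values) == 0 || nrow(m$values) == 0) stop("insufficient data: empty matrix")
  cells <- rownames(m$values)
  if (!setequal(cells, names(truth$pseudotime))) {
    stop("truth and matrix must share cell ids")
  }
  if (nrow(m$values) < 4) stop("insufficient data: need >= 4 cells")
  pt <- truth$pseudotime[cells]
  q <- stats::quantile(pt, probs = 0:4 / 4, names = FALSE)
  zones <- c("VZ", "iSVZ", "oSVZ", "CP")
  profiles <- matrix(NA_real_, 4, ncol(m$values),
                     dimnames = list(zones, colnames(m$values)))
  for (z in 1:4) {
    sel <- pt >= q[z] & pt <= q[z + 1]
    profiles[z, ] <- colMeans(m$values[sel, , drop = FALSE])
  }
  zone_reference(profiles)
}

# truncated-normal phase durations: resample below the truncation point
rtruncnorm_min <- function(n, mean, sd, lower) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate mitosis tracks with frame-grid event times
#'
#' Per-phase durations are truncated normal (truncation at one frame), rounded
#' to the frame grid with a one-frame floor, and accumulated into ordered
#' event times starting at 0, emulating ~1.1 min time-lapse annotation of
#' mitotic chromosome dynamics.
#'
#' @param groups A list of group specs, each a list with `label`, `n`, `means`
#'   and `sds`: named numeric vectors over phases
#'   `c("prophase","prometaphase","metaphase","anaphase","telophase")`
#'   (minutes; `sds` may be a single number).
#' @param frame_interval Imaging frame interval in minutes (default 1.1).
#' @param seed Integer seed.
#' @return A data.frame of `MitosisTrack` rows: `cell_id`, `group`, the six
#'   event-time columns (minutes, on the frame grid) and `frame_interval`.
#' @export
gen_mitosis_tracks <- function(groups, frame_interval = 1.1, seed = 1) {
  if (frame_interval <= 0) stop("invalid config: frame_interval must be > 0")
  phases <- c("prophase", "prometaphase", "metaphase", "anaphase", "telophase")
  set.seed(as.integer(seed))
  out <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    means <- grp$means[phases]
    if (anyNA(means) || any(means <= 0)) {
      stop("invalid config: means must be positive for all five phases")
    }
    sds <- grp$sds
    if (length(sds) == 1) sds <- stats::setNames(rep(sds, 5), phases)
    sds <- sds[phases]
    if (anyNA(sds) || any(sds < 0)) stop("invalid config: sd must be >= 0")
    n <- as.integer(grp$n)
    dur <- sapply(phases, function(p) {
      d <- rtruncnorm_min(n, means[[p]], sds[[p]], frame_interval)
      pmax(round(d / frame_interval), 1) * frame_interval  # snap to grid
    })
    dur <- matrix(dur, nrow = n, dimnames = list(NULL, phases))
    ev <- cbind(0, t(apply(dur, 1, cumsum)))
    out[[gi]] <- data.frame(
      cell_id = sprintf("%s_%03d", grp$label, seq_len(n)),
      group = grp$label,
      t_prophase_start = ev[, 1], t_congression_start = ev[, 2],
      t_plate_formed = ev[, 3], t_anaphase_onset = ev[, 4],
      t_telophase_start = ev[, 5], t_interphase_restored = ev[, 6],
      frame_interval = frame_interval,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Generate spindle-orientation tracks
#'
#' Each track samples the chromosome-plate angle (degrees from the apical
#' surface plane fold into \[0,90\]; 90 = vertical plate) every frame from
#' metaphase-plate formation through at least 2.2 min after anaphase onset.
#' Angle model: `base_angle + drift_per_min * t + N(0, jitter_sd)`, clipped to
#' \[0,90\].
#'
#' @param n Number of tracks.
#' @param base_angle Starting angle in degrees.
#' @param drift_per_min Linear drift (degrees/min).
#' @param jitter_sd Gaussian jitter sd (degrees).
#' @param metaphase_len Plate-to-anaphase time in minutes.
#' @param post_anaphase Minutes recorded past anaphase onset (>= 2.2).
#' @param frame_interval Frame interval in minutes.
#' @param seed Integer seed.
#' @return A list of `OrientationTrack` objects: each has `cell_id`,
#'   `samples` (data.frame `time_min`, `angle_deg`), `t_plate_formed`,
#'   `t_anaphase_onset`.
#' @export
gen_orientation_tracks <- function(n, base_angle = 80, drift_per_min = 0,
                                   jitter_sd = 5, metaphase_len = 8.8,
                                   post_anaphase = 3.3, frame_interval = 1.1,
                                   seed = 1) {
  if (base_angle < 0 || base_angle > 90) stop("invalid config: base_angle must be in [0,90]")
  if (jitter_sd < 0) stop("invalid config: jitter_sd must be >= 0")
  if (post_anaphase < 2.2) stop("invalid config: tracks must span >= 2.2 min past anaphase")
  set.seed(as.integer(seed))
  t_ana <- max(1, round(metaphase_len / frame_interval)) * frame_interval
  times <- seq(0, t_ana + post_anaphase + 1e-9, by = frame_interval)
  lapply(seq_len(n), function(i) {
    ang <- base_angle + drift_per_min * times +
      stats::rnorm(length(times), 0, jitter_sd)
    structure(list(
      cell_id = sprintf("track_%03d", i),
      samples = data.frame(time_min = times, angle_deg = pmin(pmax(ang, 0), 90)),
      t_plate_formed = 0,
      t_anaphase_onset = t_ana
    ), class = "OrientationTrack")
  })
}

#' Generate a cumulative-labeling curve
#'
#' Noiseless labeling index at time t is `min(GF * (t + Ts) / Tc, GF)`: a
#' linear rise from `GF * Ts / Tc` at t = 0 to the growth-fraction plateau at
#' t = Tc - Ts. Gaussian noise is added and the result clipped to \[0,1\].
#'
#' @param params A [cell_cycle_params()] (or list with `tc_h`, `ts_h`, `gf`).
#' @param times Sampling times in hours (the study design uses
#'   1, 2, 6, 24, 30/36, 48 h).
#' @param noise_sd Gaussian noise sd on the labeling index.
#' @param replicates Observations per time point (the study used triplicates).
#' @param seed Integer seed (used only if `noise_sd > 0`).
#' @return A data.frame with columns `time_h`, `labeling_index`, `replicate`.
#' @export
gen_labeling_curve <- function(params, times = c(1, 2, 6, 24, 36, 48),
                               noise_sd = 0, replicates = 1, seed = 1) {
  p <- as_cell_cycle_params(params)
  if (any(times < 0)) stop("invalid params: times must be >= 0")
  t_all <- rep(times, each = replicates)
  li <- pmin(p$gf * (t_all + p$ts_h) / p$tc_h, p$gf)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    li <- li + stats::rnorm(length(li), 0, noise_sd)
  }
  data.frame(
    time_h = t_all,
    labeling_index = pmin(pmax(li, 0), 1),
    replicate = rep(seq_len(replicates), times = length(times))
  )
}

#' Generate a toy pairwise alignment with known events
#'
#' Builds a random reference sequence and a second sequence differing by the
#' configured substitutions and indels, returned as a gapped two-record
#' alignment with the ground-truth event list attached. Fixture scale for the
#' consensus-masking stage.
#'
#' @param length Ungapped reference length.
#' @param n_snps Number of substitution sites (sampled outside indel
#'   footprints).
#' @param indels List of events `list(position=, length=, which=)`:
#'   `which = "b"` deletes `length` reference bases from the second sequence
#'   starting at 0-based reference `position`; `which = "a"` inserts
#'   `length` extra bases into the second sequence at reference insertion
#'   point `position` (gap columns in the reference).
#' @param seed Integer seed.
#' @return A `PairwiseAlignment` (see [pairwise_alignment()]) with a `truth`
#'   element listing `snps` (0-based reference positions) and `indels`.
#' @export
gen_toy_alignment <- function(length, n_snps = 0, indels = list(), seed = 1) {
  if (length < 1) stop("invalid config: length must be >= 1")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length, replace = TRUE)

  del_foot <- integer(0)
  ins_pts <- integer(0)
  for (ev in indels) {
    pos <- ev$position
    len <- ev$length
    if (is.null(ev$which) || !ev$which %in% c("a", "b")) {
      stop("invalid config: indel 'which' must be \"a\" or \"b\"")
    }
    if (len < 1) stop("invalid config: indel length must be >= 1")
    if (ev$which == "b") {
      if (pos < 0 || pos + len > length) stop("invalid config: indel out of bounds")
      foot <- pos + seq_len(len) - 1L
      if (any(foot %in% del_foot)) stop("invalid config: overlapping indel events")
      del_foot <- c(del_foot, foot)
    } else {
      if (pos < 0 || pos > length) stop("invalid config: insertion point out of bounds")
      if (pos %in% ins_pts) stop("invalid config: overlapping indel events")
      ins_pts <- c(ins_pts, pos)
    }
  }
  free <- setdiff(seq_len(length) - 1L, del_foot)
  if (n_snps > length(free)) stop("invalid config: too many SNPs for sequence length")
  snps <- sort(sample(free, n_snps))

  b_ref <- ref
  for (p in snps) {
    b_ref[p + 1L] <- sample(setdiff(bases, ref[p + 1L]), 1)
  }
  # assemble alignment columns left to right
  ins_by_pt <- list()
  for (ev in indels) {
    if (ev$which == "a") ins_by_pt[[as.character(ev$position)]] <- ev$length
  }
  a_out <- character(0)
  b_out <- character(0)
  for (p in 0:length) {
    key <- as.character(p)
    if (!is.null(ins_by_pt[[key]])) {
      len <- ins_by_pt[[key]]
      a_out <- c(a_out, rep("-", len))
      b_out <- c(b_out, sample(bases, len, replace = TRUE))
    }
    if (p < length) {
      a_out <- c(a_out, ref[p + 1L])
      b_out <- c(b_out, if ((p) %in% del_foot) "-" else b_ref[p + 1L])
    }
  }
  aln <- pairwise_alignment(paste(a_out, collapse = ""), paste(b_out, collapse = ""))
  aln$truth <- list(snps = snps, indels = indels)
  aln
}
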