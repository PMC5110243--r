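#' Pipeline configuration
#'
#' All tunables with the study's defaults: `n_top` = 100 signature genes,
#' score threshold 5.0 (log2 FPKM), network `tau` = 0.4, indel mask flank 6
#' bp, specificity thresholds `k_type` = 1 and `k_species` = 2 sd, cleavage
#' angle offset 2.2 min, EdU plateau tolerance 0.02, PCA gene selection over
#' the first 6 PCs with at most 200 genes per PC at p < 1e-3. Unknown keys
#' are rejected.
#'
#' @param ... Overrides of the defaults listed above, plus `seed`, `out_dir`,
#'   `stages` (subset of simulate, preprocess, signatures, classify, network,
#'   de, consensus, mitosis, edu), `sim` (a [sim_config()]), `n_perm`, and
#'   `edu_params` (list of named [cell_cycle_params()] to simulate and
#'   refit).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    stages = c("simulate", "preprocess", "signatures", "classify", "network",
               "de", "consensus", "mitosis", "edu"),
    n_top = 100, score_threshold = 5.0, tau = 0.4, flank = 6,
    k_type = 1, k_species = 2, offset = 2.2, plateau_tol = 0.02,
    n_pcs = 6, max_per_pc = 200, p_cut = 1e-3, n_perm = 300,
    seed = 1, out_dir = "results/pipeline",
    sim = NULL,
    edu_params = list(
      human = list(tc_h = 46.5, ts_h = 17.5, gf = 0.9),
      chimpanzee = list(tc_h = 43.8, ts_h = 12.8, gf = 0.9)
    )
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  cfg <- utils::modifyList(defaults, override)
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) stop("unknown stage: ", bad[1])
  structure(cfg, class = "PipelineConfig")
}

#' Run the composed analysis pipeline
#'
#' Runs the selected stages in dependency order on a synthetic dataset:
#' simulate -> preprocess (filter) -> signatures -> classify -> network -> de,
#' with consensus, mitosis and edu as independent branches. Every stage
#' writes its artifacts under `config$out_dir`; a `manifest.json` records the
#' full effective config, its hash, the package version and every file
#' written, which is sufficient to replay the run. A stage failure leaves a
#' `FAILED` marker beside the partial outputs and rethrows the error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `out_dir`, `files` and the loaded objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "PipelineConfig")) stop("expected a PipelineConfig")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name) {
    files <<- c(files, name)
    file.path(out, name)
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(e)
    })
  }

  stages <- config$stages
  need_sim <- any(c("preprocess", "signatures", "classify", "network", "de") %in% stages)

  if ("simulate" %in% stages || need_sim) {
    run_stage("simulate", function() {
      sim <- gen_expression(config$sim)
      state$sim <- sim
      write_expression_tsv(sim$matrix, emit("expression.tsv"))
      utils::write.csv(sim$meta, emit("cell_meta.csv"), row.names = FALSE)
      truth_df <- data.frame(
        cell_id = names(sim$truth$pseudotime),
        pseudotime = unname(sim$truth$pseudotime),
        true_type = unname(sim$truth$true_type),
        true_phase = unname(sim$truth$true_phase),
        species = unname(sim$truth$species)
      )
      utils::write.csv(truth_df, emit("truth_cells.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(gene = names(sim$truth$species_shift_genes),
                   effect = unname(sim$truth$species_shift_genes)),
        emit("truth_shift_genes.csv"), row.names = FALSE)
      zr <- gen_zone_reference(sim$truth, sim$matrix)
      state$zone_ref <- zr
      utils::write.table(t(zr$profiles), emit("zone_reference.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      tracks <- gen_mitosis_tracks(default_mitosis_groups(), seed = config$seed)
      state$tracks <- tracks
      utils::write.csv(tracks, emit("mitosis_tracks.csv"), row.names = FALSE)
      curves <- lapply(names(config$edu_params), function(sp) {
        cbind(condition = sp,
              gen_labeling_curve(config$edu_params[[sp]], replicates = 3,
                                 noise_sd = 0, seed = config$seed))
      })
      state$curves <- do.call(rbind, curves)
      utils::write.csv(state$curves, emit("labeling_curves.csv"), row.names = FALSE)
      aln <- gen_toy_alignment(length = 400, n_snps = 12,
                               indels = list(list(position = 100, length = 3, which = "b"),
                                             list(position = 250, length = 2, which = "a")),
                               seed = config$seed)
      state$aln <- aln
      write_alignment_fasta(aln, emit("toy_alignment.fasta"))
    })
  }

  if ("preprocess" %in% stages) {
    run_stage("preprocess", function() {
      state$filtered <- filter_genes(state$sim$matrix)
      write_expression_tsv(state$filtered, emit("expression_filtered.tsv"))
    })
  }

  if ("signatures" %in% stages) {
    run_stage("signatures", function() {
      m <- state$filtered
      n_top <- min(config$n_top, floor(ncol(m$values) / 2))
      sig <- pc1_signatures(m, n_top = n_top,
                            orient_genes = state$sim$truth$marker_genes$AP)
      state$sig <- sig
      utils::write.table(
        data.frame(gene = names(sig$pc1_gene_correlations),
                   correlation = unname(sig$pc1_gene_correlations)),
        emit("pc1_gene_correlations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.csv(signature_scores(m, sig, config$score_threshold),
                       emit("signature_scores.csv"), row.names = FALSE)
      state$informative <- select_informative_genes(
        m, n_pcs = config$n_pcs, max_per_pc = config$max_per_pc,
        p_cut = config$p_cut, n_perm = config$n_perm, seed = config$seed)
      writeLines(state$informative, emit("informative_genes.txt"))
    })
  }

  if ("classify" %in% stages) {
    run_stage("classify", function() {
      sim <- state$sim
      za <- zone_assign(state$filtered, state$zone_ref)
      # label the human cells with their true types to serve as the
      # correlation reference for the chimpanzee cells (and vice versa the
      # human cells are classified against themselves here: plumbing demo)
      human <- names(sim$truth$species)[sim$truth$species == "human"]
      ref <- fetal_reference(
        expression_matrix(state$filtered$values[human, , drop = FALSE], "log2p1"),
        sim$truth$true_type[human])
      ta <- celltype_assign(state$filtered, ref, genes = state$informative)
      prog <- ta$cell_id[ta$assigned_type %in% c("AP", "BP")]
      g2m <- cycle_genes_from_reference(state$filtered, prog)
      ca <- cycle_assign(
        expression_matrix(state$filtered$values[prog, , drop = FALSE], "log2p1"),
        g2m)
      meta <- sim$meta
      meta$zone <- za$zone[match(meta$cell_id, za$cell_id)]
      meta$assigned_type <- ta$assigned_type[match(meta$cell_id, ta$cell_id)]
      ph <- ca$phase[match(meta$cell_id, ca$cell_id)]
      meta$cycle_phase <- ifelse(is.na(ph), "unassigned", ph)
      state$meta <- meta
      utils::write.csv(meta, emit("cell_meta_assigned.csv"), row.names = FALSE)
    })
  }

  if ("network" %in% stages) {
    run_stage("network", function() {
      lg <- build_network(state$filtered, genes = state$informative, tau = config$tau)
      utils::write.table(edge_table(lg), emit("network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      po <- mst_pseudotime(state$filtered, genes = state$informative)
      state$pseudotime <- po
      utils::write.csv(as.data.frame(po), emit("pseudotime_order.csv"), row.names = FALSE)
    })
  }

  if ("de" %in% stages) {
    run_stage("de", function() {
      sim <- state$sim
      meta <- state$meta
      sp <- sim$truth$species[meta$cell_id]
      ap_h <- meta$cell_id[meta$assigned_type == "AP" & sp == "human"]
      ap_c <- meta$cell_id[meta$assigned_type == "AP" & sp == "chimpanzee"]
      n_h <- meta$cell_id[meta$assigned_type == "N" & sp == "human"]
      z_type <- de_zscores(state$filtered, ap_h, n_h, comparison = "AP-vs-N.human")
      z_sp <- de_zscores(state$filtered, ap_h, ap_c, comparison = "human-vs-chimp.AP")
      calls <- specificity_calls(z_type, z_sp, config$k_type, config$k_species)
      state$calls <- calls
      utils::write.table(calls, emit("specificity_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hset <- calls$gene[calls$class %in% c("AP-specific", "human-up-AP", "chimp-up-AP")]
      part <- lineage_partition(hset, hset, character(0))
      writeLines(jsonlite::toJSON(part, auto_unbox = TRUE, digits = NA),
                 emit("lineage_partition.json"))
    })
  }

  if ("consensus" %in% stages) {
    run_stage("consensus", function() {
      aln <- if (!is.null(state$aln)) state$aln else
        gen_toy_alignment(length = 400, n_snps = 12, seed = config$seed)
      mc <- mask_consensus(aln, flank = config$flank)
      write_masked_fasta(mc, emit("consensus_masked.fasta"))
      write_mask_bed(mc, emit("consensus_mask.bed"))
    })
  }

  if ("mitosis" %in% stages) {
    run_stage("mitosis", function() {
      tracks <- if (!is.null(state$tracks)) state$tracks else
        gen_mitosis_tracks(default_mitosis_groups(), seed = config$seed)
      dur <- phase_durations(tracks)
      utils::write.csv(dur, emit("phase_durations.csv"), row.names = FALSE)
      cmp <- compare_groups(dur, "prometa_meta")
      writeLines(jsonlite::toJSON(
        list(test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
             significant = cmp$significant, summary = cmp$summary),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"),
        emit("prometa_meta_comparison.json"))
      ot <- gen_orientation_tracks(n = 30, seed = config$seed)
      ori <- data.frame(
        cell_id = vapply(ot, `[[`, "", "cell_id"),
        max_range_deg = vapply(ot, orientation_range, 0),
        cleavage_angle_deg = vapply(ot, cleavage_angle, 0, offset = config$offset)
      )
      utils::write.csv(ori, emit("orientation_summary.csv"), row.names = FALSE)
    })
  }

  if ("edu" %in% stages) {
    run_stage("edu", function() {
      curves <- if (!is.null(state$curves)) state$curves else do.call(rbind, lapply(
        names(config$edu_params), function(sp) {
          cbind(condition = sp,
                gen_labeling_curve(config$edu_params[[sp]], replicates = 3,
                                   noise_sd = 0, seed = config$seed))
        }))
      fits <- lapply(split(curves, curves$condition), fit_cumulative_labeling,
                     plateau_tol = config$plateau_tol)
      out_fits <- lapply(fits, function(p) {
        list(tc_h = p$tc_h, ts_h = p$ts_h, gf = p$gf,
             plateau_onset_h = p$plateau_onset_h, r2 = p$r2)
      })
      writeLines(jsonlite::toJSON(out_fits, auto_unbox = TRUE, digits = NA),
                 emit("cell_cycle_params.json"))
      state$edu_fits <- fits
    })
  }

  # manifest: full config echo + hash (no timestamps, so reruns are
  # byte-identical under a fixed seed)
  cfg_path <- file.path(out, "config.json")
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), cfg_path)
  manifest <- list(
    package = "cortexcomp",
    version = as.character(utils::packageVersion("cortexcomp")),
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages,
    files = files
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE), file.path(out, "manifest.json"))
  invisible(list(out_dir = out, files = files, state = as.list(state)))
}

# stated-world mitosis groups: human vs chimpanzee organoid APs; the
# prometaphase+metaphase gap (~5 min) sits in metaphase
default_mitosis_groups <- function(n = 60, sd = 2) {
  phases <- c(prophase = 5.5, prometaphase = 5.5, metaphase = 9.9,
              anaphase = 2.2, telophase = 5.5)
  chimp <- phases
  chimp["metaphase"] <- 4.9
  list(
    list(label = "human_organoid_AP", n = n, means = phases, sds = sd),
    list(label = "chimp_organoid_AP", n = n, means = chimp, sds = sd)
  )
}

#' Derive a G2M gene panel from proliferating progenitors
#'
#' The panel is the top PC1-correlating genes of the progenitor subset of the
#' matrix (the convention used to split cycling from non-cycling cells):
#' PCA on progenitor cells, PC1 oriented toward higher total expression, and
#' the 100 genes most correlated with it.
#'
#' @param m An `ExpressionMatrix` (log2p1).
#' @param progenitor_cells Cell ids of the progenitor subset.
#' @param n_top Panel size (default 100).
#' @return Character vector of gene ids.
#' @export
cycle_genes_from_reference <- function(m, progenitor_cells, n_top = 100) {
  assert_log2p1(m)
  sub <- expression_matrix(m$values[progenitor_cells, , drop = FALSE], "log2p1")
  sub <- filter_genes(sub)
  n_top <- min(n_top, floor(ncol(sub$values) / 2))
  sig <- pc1_signatures(sub, n_top = n_top)
  # orient PC1 so the panel marks the high-expression (cycling) pole
  hi <- rowMeans(sub$values[, sig$nspc_genes, drop = FALSE])
  lo <- rowMeans(sub$values[, sig$neuron_genes, drop = FALSE])
  if (stats::cor(sig$pc1_cell_scores, hi - lo) >= 0) sig$nspc_genes else sig$neuron_genes
}
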