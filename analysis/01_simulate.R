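#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world with known ground truth.
#
# Emits everything the later stages consume: a two-species cells x genes
# log2(FPKM+1) matrix with an AP -> BP -> N continuum, four-zone bulk
# reference profiles, mitosis event tracks for the two species, cumulative
# EdU labeling curves, and a toy cross-species alignment.

suppressPackageStartupMessages(library(cortexcomp))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

cfg <- sim_config(seed = seed)
sim <- gen_expression(cfg)
cat(sprintf("simulated %d cells x %d genes (%d human, %d chimpanzee)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            sum(sim$truth$species == "human"),
            sum(sim$truth$species == "chimpanzee")))
cat("cell types:", paste(names(table(sim$truth$true_type)),
                         table(sim$truth$true_type), collapse = ", "), "\n")

write_expression_tsv(sim$matrix, file.path(out, "expression.tsv"))
write.csv(sim$meta, file.path(out, "cell_meta.csv"), row.names = FALSE)
write.csv(data.frame(cell_id = names(sim$truth$pseudotime),
                     pseudotime = unname(sim$truth$pseudotime),
                     true_type = unname(sim$truth$true_type),
                     true_phase = unname(sim$truth$true_phase),
                     species = unname(sim$truth$species)),
          file.path(out, "truth_cells.csv"), row.names = FALSE)
write.csv(data.frame(gene = names(sim$truth$species_shift_genes),
                     effect_log2 = unname(sim$truth$species_shift_genes)),
          file.path(out, "truth_shift_genes.csv"), row.names = FALSE)
writeLines(sim$truth$signature_genes$nspc, file.path(out, "truth_nspc_genes.txt"))
writeLines(sim$truth$signature_genes$neuron, file.path(out, "truth_neuron_genes.txt"))
writeLines(sim$truth$cycle_genes, file.path(out, "truth_cycle_genes.txt"))
writeLines(sim$truth$marker_genes$AP, file.path(out, "truth_ap_markers.txt"))

zr <- gen_zone_reference(sim$truth, sim$matrix)
write.table(t(zr$profiles), file.path(out, "zone_reference.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
cat("zone reference written (4 pseudotime-quartile bulk profiles)\n")

# mitosis tracks: human metaphase 9.9 min vs chimpanzee 4.9 min, so the
# prometaphase+metaphase difference is ~5 min, all on a 1.1 min frame grid
phases_h <- c(prophase = 5.5, prometaphase = 5.5, metaphase = 9.9,
              anaphase = 2.2, telophase = 5.5)
phases_c <- replace(phases_h, "metaphase", 4.9)
tracks <- gen_mitosis_tracks(list(
  list(label = "human_organoid_AP", n = 60, means = phases_h, sds = 2),
  list(label = "chimp_organoid_AP", n = 60, means = phases_c, sds = 2)),
  frame_interval = 1.1, seed = seed)
write.csv(tracks, file.path(out, "mitosis_tracks.csv"), row.names = FALSE)
cat(sprintf("mitosis tracks: %d cells in %d groups\n",
            nrow(tracks), length(unique(tracks$group))))

# cumulative EdU labeling curves on the study grid, in triplicate
grid <- c(1, 2, 6, 24, 36, 48)
curves <- rbind(
  cbind(condition = "human",
        gen_labeling_curve(cell_cycle_params(46.5, 17.5, 0.9), times = grid,
                           noise_sd = 0.02, replicates = 3, seed = seed)),
  cbind(condition = "chimpanzee",
        gen_labeling_curve(cell_cycle_params(43.8, 12.8, 0.9), times = grid,
                           noise_sd = 0.02, replicates = 3, seed = seed + 1)))
write.csv(curves, file.path(out, "labeling_curves.csv"), row.names = FALSE)
cat("labeling curves written (triplicates, noise sd 0.02)\n")

aln <- gen_toy_alignment(length = 400, n_snps = 12,
                         indels = list(list(position = 100, length = 3, which = "b"),
                                       list(position = 250, length = 2, which = "a")),
                         seed = seed)
write_alignment_fasta(aln, file.path(out, "toy_alignment.fasta"))
cat("toy alignment written: 400 bp, 12 substitutions, 2 indels\n")
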