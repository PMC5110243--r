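#!/usr/bin/env Rscript
# Stage 3: build the thresholded intercellular correlation network over the
# lineage genes and corroborate the AP -> BP -> N ordering with MST
# pseudotime.

suppressPackageStartupMessages(library(cortexcomp))

data_dir <- "results/data"
out <- "results"
m <- read_expression_tsv(file.path(data_dir, "expression.tsv"))
truth <- read.csv(file.path(data_dir, "truth_cells.csv"))
ap_markers <- readLines(file.path(data_dir, "truth_ap_markers.txt"))

fm <- filter_genes(m)
sig <- pc1_signatures(fm, n_top = 50, orient_genes = ap_markers)
lineage_genes <- union(sig$nspc_genes, sig$neuron_genes)

lg <- build_network(fm, genes = lineage_genes, tau = 0.4)
et <- edge_table(lg)
write.table(et, file.path(out, "network_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("network: %d cells, %d edges at rho > %.1f\n",
            nrow(fm$values), nrow(et), lg$tau))

ty <- setNames(truth$true_type, truth$cell_id)
pair <- paste(pmin(ty[et$cell_i], ty[et$cell_j]),
              pmax(ty[et$cell_i], ty[et$cell_j]), sep = "-")
n_by <- table(ty)
possible <- function(a, b) {
  if (a == b) unname(n_by[a] * (n_by[a] - 1) / 2) else unname(n_by[a] * n_by[b])
}
topo <- data.frame(
  pair = c("AP-BP", "BP-N", "AP-N"),
  edge_fraction = c(sum(pair == "AP-BP") / possible("AP", "BP"),
                    sum(pair == "BP-N") / possible("BP", "N"),
                    sum(pair == "AP-N") / possible("AP", "N")))
write.csv(topo, file.path(out, "network_topology.csv"), row.names = FALSE)
cat("edge fractions (APs connect to neurons through BPs when AP-N is lowest):\n")
print(topo, row.names = FALSE)

po <- mst_pseudotime(fm, genes = lineage_genes)
write.csv(as.data.frame(po), file.path(out, "pseudotime_order.csv"), row.names = FALSE)
rho <- cor(po$position, truth$pseudotime[match(po$cell_id, truth$cell_id)],
           method = "spearman")
cat(sprintf("MST pseudotime vs truth: Spearman rho = %.3f (|rho| counts; %d backbone cells)\n",
            rho, sum(po$backbone)))
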