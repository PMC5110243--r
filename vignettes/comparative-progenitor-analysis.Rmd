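---
title: "Comparative analysis of cortical progenitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of cortical progenitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexcomp)
```

# Scope

`cortexcomp` re-implements, as a tested and reusable pipeline, the bespoke
computations of a comparative study of human and chimpanzee cortical
progenitors in cerebral organoids: classification of single-cell
transcriptomes against bulk-zone and labelled fetal references, PC1-derived
gene-signature scoring, a thresholded intercellular correlation network with
a minimum-spanning-tree (MST) pseudotime, cross-species consensus-sequence
masking, threshold-based differential-expression calling, mitotic-phase and
spindle-orientation quantification, and cell-cycle parameter estimation from
cumulative EdU labeling. A seeded synthetic-data generator replaces the
deposited sequencing and imaging data, so every stage is testable against a
known ground truth at desk scale.

The `analysis/` directory holds the numbered drivers that run these stages in
order; all computation lives in the package so the test suite and the
acceptance script exercise the same code.

# Expression data and preprocessing

All transcriptomic operations run on cells × genes matrices of
log2(FPKM + 1) values; the container carries an explicit scale flag and every
analysis function refuses a matrix that has not been through
`log_transform()`. "Expressed" always means value > 0, which on this scale is
FPKM > 0.

`filter_genes()` keeps genes expressed in **strictly more than** two cells
(a gene seen in exactly two cells is removed) and with non-zero variance
across cells. The variance test is qualitative, computed with denominator
*n*; any non-constant gene passes. Filtering is idempotent and preserves gene
order. The threshold is applied to the joint (combined-species) matrix.

# Signatures and informative genes

`pc1_signatures()` runs PCA on the filtered reference (genes centered, not
variance-scaled) and correlates each gene with the PC1 cell scores; the top
and bottom `n_top` genes (default 100) form the NSPC-like and neuron-like
signatures. PCA sign is arbitrary, so orientation is fixed by a declared
marker list (`orient_genes`): PC1 is flipped until those markers correlate
positively. On the 200-gene synthetic world the drivers use `n_top = 50`,
which keeps the two signatures disjoint at the same relative depth as 100
genes against a ~12,000-gene transcriptome.

`signature_score()` is the threshold statistic: the number of signature genes
expressed above log2 FPKM 5, divided by the number of *all* genes above that
threshold in the cell. The cutoff is interpreted on the log2(FPKM + 1) scale
as value > 5.0 — at that magnitude the +1 shifts the cutoff by under 0.05
log2 units. Cells with an empty denominator get `NA` scores (flagged, never
0).

`select_informative_genes()` substitutes a permutation test for the original
pipeline's unspecified PCA-significance procedure: for each of the first 6
PCs, a gene's loading magnitude is compared with magnitudes recomputed after
shuffling the cell labels (equivalently, permuting the PC score vector), and
genes with Monte-Carlo p below `p_cut` (default 1e-3) are kept, at most 200
per component. Two numerical choices matter here:

* the p-value uses the plain `k/B` estimator rather than `(k+1)/(B+1)`; with
  the +1 correction no gene could ever reach p < 1e-3 at the default 500
  permutations;
* because the PC scores are *fixed* while the gene is permuted, the test is
  anti-conservative for the leading components — PC1 is chosen to maximize
  variance, so observed loadings are inflated relative to this null (the
  selection bias the jackstraw literature addresses). On pure noise the
  selected fraction sits a small factor above `p_cut`, which the test suite
  pins down. The strict default cutoff still prunes essentially everything
  under the null.

# Classification

**Zones.** Each cell is Spearman-correlated with the four microdissected-zone
bulk profiles (VZ, iSVZ, oSVZ, CP) over the shared genes and assigned the
argmax zone. The four correlations are also z-scaled within each cell for
display; scaling never changes the argmax. Correlations are computed on the
intersection of gene ids (dropped counts are logged); a constant cell or
profile makes the correlation undefined and the cell is flagged
`unassigned`. A minimum of 10 shared genes is enforced.

**Cell types.** `celltype_assign()` Pearson-correlates each query cell with
every labelled reference cell over a gene subset and assigns the collapsed
type (AP/BP/N) of the best-correlating reference cell; subtype labels such as
"AP1" (APs in G2-M) collapse by stripping trailing digits. Argmax ties break
deterministically toward the lowest reference cell id, with a warning.

**Cycle phase.** `cycle_assign()` hierarchically clusters the cells of one
class on a G2M gene panel with correlation distance (1 − Pearson), cuts the
tree into three clusters, and labels the highest-mean cluster G2M, the lowest
G1, and the middle `intermediate` (excluded from differential expression).
k = 3 is the smallest cut yielding the three categories the original analysis
used. The linkage is **Ward** (`ward.D2`), a deliberate design choice: the
source names only the distance metric, and average linkage chains the two
phase clusters into one whenever the panel's G2M amplitude profile is
near-collinear with its baseline profile, making the forced 3-cut collapse
onto outliers. Ward is robust to exactly that geometry. Fewer than three
distinct expression patterns ⇒ every cell `intermediate`.

The G2M panel itself is configurable. The derived route
(`cycle_genes_from_reference()`: top PC1-correlating genes of a
proliferating-progenitor subset) presumes the cycle dominates the
progenitors' leading component; in worlds (or datasets) where the residual
differentiation gradient dominates instead, a curated cycle gene list should
be passed — the analysis drivers do the latter.

# Lineage network and MST pseudotime

`build_network()` draws an undirected edge between two cells whenever the
Pearson correlation of their profiles over the lineage gene subset exceeds
τ = 0.4, storing the correlation as the edge weight; constant cells are
excluded and logged. The lineage subset used by the drivers is the union of
the two PC1-derived signatures — the genes that define the
progenitor-to-neuron axis — matching the original network construction, which
reused the genes discovered by PCA of the reference rather than the broader
6-PC clustering set.

`mst_pseudotime()` builds the complete graph with distance 1 − Pearson, takes
its minimum spanning tree, extracts the weighted diameter (longest shortest
path) as the lineage backbone, projects every other cell onto its nearest
backbone node (tree distance), and orders cells by their projected position.
The ordering is defined up to global reversal. Equal-weight edges are
tie-broken by the lexicographic cell-id pair, implemented as an epsilon
(1e-12 per rank) far below correlation resolution, so results are
deterministic. No low-dimensional embedding is computed: the testable claim
is the backbone ordering, not the layout. Cells whose correlations are
undefined are removed with a warning, and a disconnected graph is ordered per
component.

The MST is the noise-sensitive stage of the pipeline: in a noisy metric the
tree grows hub-dominated, the diameter shortens, and projections coarsen.
The recovery property is therefore stated (and tested) as the **median**
absolute Spearman correlation with true pseudotime across seeded replicate
worlds, which is the estimator a recovery claim actually needs; single seeds
scatter around the threshold.

# Consensus masking

`mask_consensus()` produces the two-species consensus in reference (`seq_a`)
coordinates, 0-based half-open. Two rules: (i) alignment columns where both
bases are present but differ are masked; (ii) every maximal gap run — in
either sequence — masks the reference positions it overlaps plus 6 reference
bases of flank on each side. An insertion in the second sequence has zero
reference width, so its flank extends from the insertion point both ways
(a 2·flank window). The flank is attached to the full gap run, not to each
gap column, matching the intent of removing indel-adjacent mapping
artefacts. Intervals are clipped to bounds and merged; masked bases become N.
Ambiguity codes other than N are rejected at parse time so the contract stays
checkable. Only the reference frame is emitted; the other frame is obtained
by swapping the inputs. Outputs are FASTA plus a BED of mask intervals (BED
is natively 0-based half-open).

# Differential expression

`de_zscores()` scores each gene with a pluggable two-group backend; the
default is the continuity- and tie-corrected normal deviate of the
Mann-Whitney U statistic, signed by the direction of the rank-sum deviation
(positive = higher in the first group; human is the first group in species
comparisons, so positive species z = higher in human). The heavier Bayesian
dropout model used originally is deliberately not reimplemented: downstream
logic consumes only z-scores, and the thresholds are the contribution being
reproduced. The sign convention differs microscopically from "direction of
the group-A median": the rank-sum direction is always defined, is
antisymmetric under group exchange, and agrees with the median direction
whenever the latter is defined. Genes that are all-zero in both groups score
0 and are flagged untested rather than dropped.

`specificity_calls()` applies the sd thresholds: a gene is AP-specific
(N-specific) when its cell-type z exceeds the mean ± 1 sd of the cell-type z
distribution, and a species call additionally requires the species z beyond
mean ± 2 sd *and* cell-type specificity on the matching axis. Means and sds
are taken over all tested genes. A degenerate (zero-sd) z distribution makes
no calls, with a warning.

`ap_specificity_score()` — the inputs are stated by the source but not the
functional form; the recorded stand-in is
`mean_AP − max(mean_iPSC, mean_EC)` in log2 units, higher meaning more
AP-restricted. `lineage_partition()` classifies the human/chimp call sets
against a mouse set by plain set arithmetic, with proportions over the
human-chimp union.

# Mitosis timing and spindle orientation

Tracks carry six manually-annotated event times on a ~1.1 min frame grid
(prophase start, congression start, plate formed, anaphase onset, telophase
start, interphase restored); `phase_durations()` differences them, with
prometaphase + metaphase and the total (the sum of all phases) derived.
Cumulative sums of the output reproduce the event times exactly.

`compare_groups()` uses the two-sided Mann-Whitney U test for two groups
(exact whenever sample sizes permit and there are no ties) and
Kruskal-Wallis with Dunn's pairwise post-hoc for three or more, reporting
group n, mean ± SEM (sd/√n, sd with denominator n − 1), medians, and
significance at p < 0.05. Dunn's z is the tie-corrected rank-mean contrast;
no multiplicity adjustment is applied by default (none is named by the
source), but any `p.adjust` method can be requested.

Spindle orientation uses angles in [0, 90]° relative to the apical surface
plane (90° = vertical chromosome plate). `orientation_range()` is the
max − min angle between metaphase-plate formation and anaphase onset
(inclusive window, nearest-frame, no sub-frame interpolation);
`cleavage_angle()` reads the sample nearest 2.2 min after anaphase onset,
with equidistant samples resolving to the earlier one (distances are rounded
at 1e-6 min so floating-point noise cannot flip a tie).

# Cumulative EdU labeling

The labeling index follows a linear rise to a plateau:
LI(t) = min(GF·(t + Ts)/Tc, GF), so LI(0) = GF·Ts/Tc and the plateau starts
at t = Tc − Ts. `fit_cumulative_labeling()` inverts this graphically, as the
original read-off did: the plateau is the terminal flat segment — anchored at
the earliest time attaining the curve maximum and extended backwards through
times within `plateau_tol` (default 0.02) of it — detected on **per-time
means** so that replicate noise comparable to the tolerance cannot truncate
it; GF is the mean of the plateau observations; a least-squares line through
the strictly pre-plateau *individual* points (replicates are not averaged for
the fit) gives Ts = intercept/slope (the x-intercept is −Ts),
Tc − Ts = (GF − intercept)/slope, and Tc = GF/slope. Non-positive slopes and
plateau-less curves are errors. The round-trip identity fit(predict(θ)) = θ
is exact for noiseless sampling with `plateau_tol = 0`; any positive
tolerance absorbs near-plateau points of a densely-sampled rise.

The growth fraction has no printed value in the source (it appears only as
figure arrowheads); the synthetic world uses GF = 0.9, a typical plateau for
proliferating PAX6+TBR2− organoid progenitors, chosen once.

# The synthetic stated world

`gen_expression()` uses the simplest model that reproduces every structure
the downstream stages assume: additive log-scale programs plus Gaussian
noise, Bernoulli dropout (independent of magnitude), and a clip at zero.
Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| cells per species | 100 | comparable to the per-species cortical-cell counts of the study |
| genes | 200 | desk scale; block shares mirror a filtered transcriptome |
| signature genes | 40 + 40 | the differentiation program dominates the transcriptome's variance |
| type / species effect | 2 log2 units | the effect sizes the recovery examples state |
| cycle effect | 1 log2 unit | lineage dominates cycle, as in the reference PCA where PC1 is the lineage |
| noise sd | 0.25 | deep full-length (C1/SMARTer) FPKM libraries, not droplet data |
| dropout | 0.02 | post-filter dropout load of deep full-length libraries |
| P(G2M) | 0.3 progenitors / 0.05 neurons | progenitors cycle, neurons mostly do not |

Pseudotime is uniform on [0, 1] with types at terciles, so mean pseudotime
rises AP → BP → N by construction. Cycle-panel genes get per-gene baselines
U(0, 2) and amplitudes `cycle_effect`·U(0.25, 1.75): a panel with a flat
profile would make correlation-based phase clustering impossible for any
method, since Pearson sees only profile shape. Species-shift genes ride the
AP gradient plus a +2 log2 shift in human APs, making them both AP-specific
and human-up — the joint condition the specificity caller requires.

What the generator does **not** emulate: count-level sampling noise,
magnitude-dependent dropout, batch and organoid-of-origin effects, doublets,
and continuous (rather than two-state) cycle progression. A green recovery
test therefore establishes that the pipeline's logic recovers a planted
structure of realistic effect size under idealized noise — not that it would
perform identically on droplet-level sparsity.

Mitosis tracks are cumulative sums of truncated-normal phase durations
(truncation at one frame prevents degenerate phases), rounded to the frame
grid. The stated world gives human APs a 9.9 min metaphase versus 4.9 min in
chimpanzee with all other phases equal (5.5/5.5/2.2/5.5 min), so the ~5 min
prometaphase+metaphase gap arises from metaphase alone, sd 2 min, n = 60 per
group — the design whose power the suite verifies.

# Determinism

Every generator takes one integer seed and uses no hidden global state;
identical configurations are bit-identical, and a fixed-seed pipeline run is
byte-reproducible on disk (the run manifest echoes the full configuration and
its hash, which suffices to replay a run). Analyses are deterministic given
their inputs; the only stochastic analysis component, the permutation test,
takes its own seed.

# Known limitations

* The MST backbone is a global-structure summary; its projection granularity
  caps rank agreement with a continuous pseudotime at roughly 0.95 even in a
  noiseless world, and hub formation degrades it in high-noise worlds.
* The rank-sum backend saturates at small group sizes (|z| ≤ ~5 for 17 vs 17
  cells), so z magnitudes are not comparable across group-size regimes.
* The permutation gene selector inherits the fixed-PC selection bias
  described above; its p-values are screening scores, not calibrated
  significance levels.
* `plateau_tol` trades robustness against plateau-onset bias: tolerance bands
  absorb late-rise points when sampling is dense near Tc − Ts.
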