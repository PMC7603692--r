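---
title: "Methods: codon-model analysis of WGD paralog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-model analysis of WGD paralog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`paraselect` studies the fate of gene duplicates retained after a
whole-genome duplication (WGD), modeled on the Ep300a/Ep300b pair that
teleost fishes kept from their lineage-specific WGD. The pipeline covers
homolog curation from blast-style hit tables, alignment post-processing
(length filtering, gap-based trimming, consensus building,
back-translation to codons), tree comparison, codon-model selection
inference at branch, clade and site level, mapping of selected sites onto
conserved-domain annotations, and correlation of paralog tissue-expression
profiles. A seedable simulator generates every input with known ground
truth, so the whole chain is testable without any sequence download.

# The substitution model

All selection inference rests on a GY94-type codon substitution model over
the 61 sense codons of the standard nuclear code. The instantaneous rate
from codon $i$ to $j$ is

$$
q_{ij} = \pi_j \cdot \begin{cases}
0 & \text{more than one position differs} \\
1 & \text{synonymous transversion} \\
\kappa & \text{synonymous transition} \\
\omega & \text{nonsynonymous transversion} \\
\kappa\omega & \text{nonsynonymous transition,}
\end{cases}
$$

with stationary codon frequencies $\pi$ (F3x4 with 0.5 pseudo-counts per
nucleotide per codon position by default; equal frequencies available),
transition/transversion ratio $\kappa$ and selection pressure
$\omega = d_N/d_S$. Generators are rescaled so one unit of branch length
is one expected substitution per codon site under the model's mixture
weights; for branch-partitioned models the rescaling is per partition, so
the invariant "unit expected rate under the fitted weights" holds within
each partition. Tree likelihoods use Felsenstein pruning (implemented in
C++ over eigen-decomposed reversible generators); gaps and IUPAC
ambiguity codes are treated as missing data by summing over compatible
codon states.

# Model families and tests

* **M0** — one $\omega$ for all sites and branches. Fitted with $\kappa$
  and a global branch-length scale; its estimates ($\kappa$, $\pi$,
  scaled branch lengths) are the baseline that every other fit holds
  fixed. This is standard practice and keeps the mixture fits
  low-dimensional; per-model branch-length re-optimization is deliberately
  not attempted.
* **M7 / M8** — site-class models for pervasive positive selection. M7
  draws $\omega \sim \mathrm{Beta}(p, q)$ discretized into $K = 10$
  equal-probability bins represented by their median quantiles; M8 adds a
  spike class $\omega_s \ge 1$ with weight $1 - p_0$. The LRT uses
  $\chi^2_2$ (the conventional, conservative choice rather than a
  boundary mixture). Sites are flagged by naive empirical Bayes (NEB)
  posterior of the spike class above 0.95 (tag **M**).
* **M2a_rel** — three shared site classes $\omega_0 \le 1$,
  $\omega_1 = 1$, free $\omega_2$; the null of the clade model.
* **Clade model C** — classes 0 and 1 shared, class-2 $\omega_2$
  estimated separately per branch partition (two labeled clades plus the
  unlabeled background by default, following the convention of labeling
  all internal and external branches of the two clades of interest; the
  stem branch is excluded unless requested). LRT against M2a_rel with
  $\text{partitions} - 1$ degrees of freedom.
* **Selection-intensity (RELAX-style) test** — reference branches carry
  $(\omega_0, 1, \omega_2)$; test branches carry
  $(\omega_0^k, 1, \omega_2^k)$. $k > 1$ means intensified, $k < 1$
  relaxed selection; the null fixes $k = 1$ (df 1). The mean
  $\omega = \sum_i p_i \omega_i$ is reported per partition. Unlike the
  full published method, synonymous-rate variation across sites is not
  modeled; this simplification is intentional and documented here.
* **Episodic branch test** — a fixed two-class variant of the adaptive
  branch-site approach: the focal branch carries $(\omega^- \le 1$ with
  weight $p$; $\omega^+ \ge 1)$, all other branches one free background
  $\omega$. Null: $\omega^+ = 1$; reference
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. The sweep mode tests every
  branch and reports uncorrected and Holm-corrected p values; a branch is
  called positively selected at uncorrected $p < 0.05$, with corrected
  flags carried alongside.
* **Episodic site test** (tag **E**) — per site, each branch
  independently draws $\omega^-$ (weight $p^-$) or a free $\omega^+$, so
  the per-branch transition matrix is the weight-mixed pair; the null
  constrains $\omega^+ \le 1$. Per-site LRT against $\chi^2_2$ by
  default (configurable), flagged at $p < 0.05$.
* **Grid empirical-Bayes site test** (tag **F**) — site likelihoods on a
  fixed 20-point $\omega$ grid (0, log-spaced 0.05–10, and 1), grid
  weights estimated by EM with a symmetric Dirichlet(0.5) regularizer,
  sites flagged at posterior $P(\omega > 1) > 0.9$. This is a maximum a
  posteriori grid variant of the published MCMC approach.

The adaptive model-complexity selection of the published branch-site
method and MCMC posterior sampling are out of scope by design; the fixed
two-class and grid-EB variants implemented here are documented
simplifications.

# Optimization and numerical choices

Fits use `nlminb` on smoothly transformed parameters: bounded logistic
maps for rates ($\omega \in [0, 50]$, $\kappa \in [0.1, 20]$,
$k \in [0.02, 50]$, beta shapes in $[0.005, 100]$) and stick-breaking for
simplex weights (floored at $10^{-6}$). Each fit runs three deterministic
starts (a data-informed point, a neutral-ish point, and a dispersed
point); nested alternatives are additionally warm-started at the null
MLE, and the nesting inequality
$\log L_{\text{alt}} \ge \log L_{\text{null}}$ is enforced by falling
back to the null solution if optimization ends below it. Clade-model
starts are seeded from a cheap one-class-per-partition fit, which proved
necessary: the three-class likelihood surface is multimodal and naive
starts can merge the purifying and divergent classes. Convergence
tolerance is $10^{-8}$ on the log-likelihood; results are reproducible
bit-for-bit for a given seed. Degenerate inputs (invariant alignments)
drive the branch scale to its floor and are flagged unidentifiable rather
than erroring.

Ties and edge cases elsewhere are resolved deterministically: alignment
trimming removes the rightmost column among equally gappy ones and the
target length is rounded up; consensus ties break alphabetically and a
gap majority falls back to the most frequent residue (a fully gapped
column is an error); hit-selection rank ties break by accession; the
two-sided Fisher p value uses hypergeometric probability ordering with a
$10^{-12}$ tie slack.

# The simulator and what it does (not) emulate

`simulate_codon_alignment()` draws a site class per codon from the model
proportions, the root codon from $\pi$, and evolves states along the tree
with the partition-appropriate transition matrices — matching the fitting
side exactly, including the per-partition rate normalization. It never
emits stop codons and is a pure function of (parameters, seed).
`simulate_expression_tables()` emulates the structure of tissue
read-count tables behind paralog expression comparisons: a shared
lognormal tissue profile, per-copy noise (sd 0.3), a log-fold shift of
the designated fast copy in a configurable fraction of tissues, and
negative-binomial counts (dispersion 0.1). `make_curation_fixture()`
emits blast-style tables with decoy descriptions, disallowed organisms
and mixed sequence statuses, together with the selection implied by the
curation rules.

What passing tests therefore show is internal consistency: the fitting
machinery recovers the parameters of data generated under its own model
assumptions at realistic sizes. Real alignments violate these
assumptions — alignment error, indels, synonymous-rate variation,
among-site rate autocorrelation, codon-usage heterogeneity across
lineages — so recovery here is a necessary, not sufficient, condition
for trustworthy inference on real data.

# Problem sizes used by the test suite

Simulation-based suites run at sizes chosen to exercise the study
conditions while keeping a full test run on one CPU tractable: M0
recovery uses 20 replicates of 8 taxa x 300 codons ($\omega = 0.3$,
$\kappa = 2$); M8-vs-M7 calibration 12 replicates of 8 x 200 under the
M7 null; clade-model recovery 10 replicates of 12 x 400 with
$\omega_2 = 0.2$ vs $0.5$ ($p_2 = 0.4$); the selection-intensity test 10
power replicates ($k = 3$) and 10 calibration replicates ($k = 1$) of
10 x 200; site-detection precision one 12 x 300 dataset with
$\omega_s = 4$ on 10% of sites. Deterministic plumbing properties
(trimming, consensus, back-translation, Fisher vs the reference
implementation) run on 1,000 generated cases.

# Known limitations

* Branch lengths are estimated once (M0) and fixed; strong model
  violations can bias downstream mixture estimates.
* The episodic tests are fixed-complexity variants; their p values are
  conservative by construction and should be read as screening values,
  as in the exploratory uncorrected-p convention they support.
* NEB posteriors ignore parameter uncertainty (no Bayes empirical Bayes
  intervals).
* The RF-based tree comparison treats trees as unrooted and, for
  polytomies, normalizes by the actual bipartition counts rather than
  $2(n-3)$. The shared-edge fraction is reported both over internal
  bipartitions and over the full edge set (terminal edges included), the
  latter matching how edge-wise comparison tools count edges.
* Expression correlations are computed on RPKM (no log transform) with
  intersection semantics over tissues, as the correlations they mirror
  were; a `log1p` option is not provided because the reference analysis
  used raw RPKM.

# A worked example

```{r, eval = FALSE}
library(paraselect)

# simulate a clade-divergent alignment and recover the divergence
tree <- ape::rtree(12, br = function(n) runif(n, 0.05, 0.25))
ntip <- 12
kids <- tree$edge[tree$edge[, 1] == ntip + 1, 2]
node <- kids[kids > ntip][1]
inv <- branch_inventory(tree)
clade1 <- ape::extract.clade(tree, node)$tip.label
clade2 <- setdiff(tree$tip.label, clade1)
ltree <- label_clades(tree, list("#1" = clade1, "#2" = clade2))

sim <- simulate_codon_alignment(
  ltree,
  sim_spec(family = "CmC", kappa = 2, omegas = c(0.05, 1, NA),
           props = c(0.45, 0.15, 0.4),
           omega2_by_partition = c("#1" = 0.2, "#2" = 0.5,
                                   background = 0.35)),
  n_codons = 400, seed = 1)

res <- fit_clade_model_c(sim$alignment, ltree)
res$fit$mle$omega2   # per-partition omega2; "#2" should exceed "#1"
res$lrt$p            # clade model C vs M2a_rel
```
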