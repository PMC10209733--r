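---
title: "Methods: chromatin priming analysis for paired single-cell multiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin priming analysis for paired single-cell multiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromprime)
```

## Scope and model

`chromprime` implements the computational core of a lineage-specification
study design built on paired single-cell chromatin accessibility (scATAC)
and expression (scRNA) measurements of early embryonic cells: epiblast (EPI)
and trophectoderm (TE) lineages progressing through ordered developmental
stages. The package asks three questions of such data:

1. **Which peaks regulate which genes?** Cis peak-to-gene links are Pearson
   correlations between peak accessibility and gene expression across paired
   cells, judged against an empirical null of *trans* correlations; genes
   accumulating many significant links are *domains of regulatory chromatin*
   (DORCs).
2. **Which transcription factors drive a lineage?** TF-target networks join
   a TF to a gene through peaks that are both significantly linked to the
   gene and carry the TF's motif, with the summed squared correlation as the
   edge weight; TFs are ranked by the sum of their degree, closeness and
   eigenvector centrality ranks ("driving potential").
3. **Does chromatin open before genes turn on?** Stage-wise gained/lost
   accessible peaks and a pseudotime lead-lag classifier operationalize
   chromatin priming.

Because real embryo data require raw-sequencing-scale processing, the
package ships a synthetic paired-multiome generator with planted ground
truth; every pipeline stage is validated against what was planted.

## The synthetic generator

Each cell belongs to a lineage and an ordered stage and has a pseudotime
equal to its stage index plus uniform jitter. Each gene $g$ carries a latent
per-cell program $u_g$, standard normal across cells plus (for planted
regulon members) a lineage-specific effect $\beta\gamma^{s-1}$ at stage $s$
(defaults $\beta = 1.5$, $\gamma = 1.6$), so the planted lineage contrast
amplifies across stages. Expression is lognormal,
$x_{gc} = \exp(\mu_g + \sigma_u u_{gc} + \sigma_\epsilon \epsilon_{gc})$,
reported in TPM-like units. Each peak $p$ carries a latent $v_p$; counts are
Poisson, $a_{pc} \sim \mathrm{Pois}(d_c\, m_p\, e^{\sigma_p v_{pc} -
\sigma_p^2/2}\, \omega_{pc})$ with a lognormal cell depth factor $d_c$, a
per-peak mean $m_p$, and a gain/loss multiplier $\omega_{pc}$ that drops to
`closed_mult` on the silent side of a planted stage boundary.

A planted link $(g, p, \rho)$ sets
$v_p = \rho\, u_g + \sqrt{1 - \rho^2}\,\varepsilon$. Count sampling and the
log1p transform attenuate the realized Pearson correlation below $\rho$; the
default noise scales (`peak_mean = 25`, `peak_sig_sd = 1`,
`expr_noise_sd = 0.15`) were calibrated once so that the attenuation factor
is about 0.9, keeping the empirical correlation of a $\rho = 0.6$ link
within $\pm 0.15$ of its target at a few hundred cells. A planted lag gives
a gene a sigmoidal activation $\operatorname{logit}^{-1}(k(t - t_0))$ along
pseudotime and shifts its promoter peak's activation $\delta$ units earlier;
for these genes both modalities are linear in the activation (rather than
exponential) so that min-max-normalized curves of the two modalities cross
0.5 at comparable points and the planted lead is identifiable.

Fragment records are expanded from the in-peak count matrix — one record per
count unit, placed uniformly inside the peak — plus off-peak records sampled
outside peaks at a configurable fraction (default 0.35 of usable fragments,
setting FRiP near 0.65). The promoter peak of each gene coincides with the
500-bp promoter window, which puts the median promoter fraction near 15%,
comparable to what high-quality single nuclei show in practice. Five percent
of cells are planted at one-third depth so the fragment-count filter has
something to reject. The genome is a declaration of three 10-Mb
chromosomes; genes are laid out round-robin at 40-kb spacing so the ±25-kb
cis windows of neighbouring genes do not share peaks at the default panel
density, and trans-chromosome nulls always exist.

**What the generator does not emulate:** read-level sequence, doublets,
batch effects, GC or width biases in peaks, bursty transcription, cell-type
proportions changing along a trajectory, and real motif co-occurrence
structure (background motif hits are independent Bernoulli draws). Passing
tests therefore demonstrate correctness of the statistical machinery under a
clean generative model, not robustness to every artifact of real embryo
data.

## QC conventions

Usable fragments are all post-deduplication records attributed to a barcode
(alignment and deduplication happen upstream of this package). A fragment
counts toward a region — promoter, peak, or gene-activity window — when the
two intervals overlap by at least one base; a record with count $c$
contributes $c$ to every tally. The promoter is the symmetric 500-bp window
(TSS ± 250 bp), unshifted by strand, clipped at chromosome ends. Cells pass
when usable fragments exceed 10,000 and the promoter fraction exceeds 10%,
both strictly. The RNA-side filter removes cells with fewer than one
million mapped reads or at most 2,000 genes above 1 TPM; on synthetic
panels of a few hundred genes the detected-gene cutoff must be rescaled by
the caller (the analysis scripts use half the panel size).

## Peak-to-gene linking and DORCs

A peak is a candidate for a gene when any part of it lies within ±25 kb of
the TSS. Both matrices are library-size normalized (per cell, to the median
total) and log1p transformed by default; Pearson correlations are computed
across cells, optionally pooled into metacells of `aggregate_k` cells drawn
within lineage × stage groups. The default `aggregate_k = 1` reflects that
synthetic (and truly paired) cells need no aggregation; sparse real data
would raise it.

The null for gene $g$ is the set of correlations between $g$'s expression
and `n_null = 100` peaks sampled from other chromosomes. Significance is a
two-sided normal test of $z = (r - \mu_{null})/\sigma_{null}$; the normal
approximation on the null moments is stable at 100 nulls where an empirical
quantile would be coarse, and the choice is recorded in the link table's
metadata. One consequence worth naming: with an estimated null, rejections
of true nulls occur slightly above the nominal rate at finite `n_null`, and
the calibration test verifies the rate falls within the 99% binomial band
of $\alpha = 0.05$ over ~2,000 candidate pairs. Zero-variance genes or
peaks are skipped and reported, never silently dropped. A gene with
strictly more than 10 significant links is a DORC; at the default 4 cis
peaks per gene DORCs are impossible by construction, so DORC analyses use
the dense-panel design (12 cis peaks per gene) exercised by the acceptance
script.

Library-size normalization couples genes through the per-cell totals, so
exact invariance of a link to rescaling one gene holds for the raw Pearson
path (`normalize = "none"`); with the default normalization the coupling is
negligible at realistic panel sizes but not identically zero.

## Differential features and motif enrichment

One-vs-rest comparisons use a Wilcoxon rank-sum test after excluding
features detected in fewer than 20% of cells on both sides (`min.pct`
convention). Single-cell toolkits often default to a logistic-regression
test for this step; the rank-sum choice here is distribution-free and
reproducible, and the test used is recorded in the output. Log fold changes
are natural logs of pseudocounted means of size-normalized values, fixed so
results are comparable across runs. BH correction is applied within each
group's tested set. Motif enrichment of a peak set is a hypergeometric
upper-tail test against all non-foreground peaks (GC- or width-matched
backgrounds are out of scope), with fold enrichment the ratio of hit rates.

## Networks, centralities, driving potential

An edge (TF, gene) requires at least one peak that is both significantly
linked to the gene and motif-hit by the TF; its weight is
$\sum_{\text{peaks}} r^2$. Centralities are computed on the undirected,
unweighted projection of the bipartite TF-target graph (target nodes
included; the weighted linkage scores stay available in the edge table for
auditing, and a weighted ranking can be built from them if wanted). Degree centrality is degree/(n−1). Closeness uses the
Wasserman–Faust component scaling so disconnected networks — common for
small marker sets — are handled without infinities. Eigenvector centrality
is power iteration per connected component on $A + I$; the identity shift
leaves eigenvectors unchanged while guaranteeing convergence on bipartite
components, whose unshifted adjacency spectra are symmetric about zero and
make naive power iteration oscillate. Components are combined by scaling
each component's unit vector by its spectral radius relative to the largest
component's. Tolerance 1e-8, at most 1,000 iterations, nonnegative output.

Driving potential ranks each centrality descending within the TF subset
(most central = rank 1, ties averaged), sums the three ranks, and sorts
ascending with ties broken by TF name. The polarity — smallest rank sum =
strongest driver — is a deliberate reading of "the higher the rank, the
more influential"; since only the ordering matters downstream, the raw
centralities are reported alongside so either polarity can be audited.

## Stage dynamics and priming

A peak is accessible in a stage when strictly more than 25% of the stage's
cells have a nonzero count. Gained and lost peaks across an ordered
transition are plain set differences; changed peaks are attributed to every
gene whose ±25-kb TSS window overlaps them (reusing the linking window
rather than a nearest-gene rule, recorded in configuration) and bucketed
1 / 2 / ≥3 per gene.

The pattern-1-versus-pattern-2 distinction (chromatin precedes expression
versus concurrent) is operationalized as a half-activation lag: both
pseudotime curves are min-max normalized, smoothed with a centered
three-bin moving average, and assigned the first bin where the smoothed
curve crosses 0.5 from below. Pattern 1 is called when accessibility's
half-activation precedes expression's by more than `lag_tol` (default one
bin). Curves that never up-cross 0.5 — already-active, silent, or
monotone-decreasing genes — are flagged unclassifiable rather than forced
into a pattern. This distinction is usually made visually from clustered
pseudotime heatmaps; the half-activation lag turns it into a statistic a
test can check. Bin occupancy
matters: at fewer than ~15 cells per bin the noisier accessibility curve is
systematically depressed by min-max normalization (its maximum bin is
inflated), biasing the lag estimate late; the validation configurations use
~18-24 cells per bin and the workflow scripts use 20 bins at 150 cells.

## Driver genes and lineage TFs

Stage-pair DEG tables (EPI minus TE log fold change per ordered stage pair)
are computed for two datasets — in the synthetic study, two replicate
generations playing the roles of in vitro and in vivo cohorts. A gene
qualifies as divergence-amplifying when its log fold change keeps a
constant nonzero sign and strictly increases in magnitude across the
ordinals. Whether divergence selection should also demand sharpening
significance is genuinely open; the magnitude rule is the default and an
optional flag additionally requires nonincreasing p-values. Genes absent from an ordinal count as zero log fold
change and thus never qualify. Drivers are the side-respecting intersection
of the two datasets' selections. Difference ratios compare the absolute
EPI-vs-TE log fold change at a post-implantation phase to a
pre-implantation phase, on expression and on gene activity; the
phase-to-stage mapping is a required argument, never inferred. Lineage TFs
must be enriched (p < 0.01) among peaks linked to one side's drivers, not
enriched (p > 0.01) on the other side, and more fold-enriched on their own
side.

## Problem sizes and determinism

Validation runs use: ~400 cells for link calibration (2,080 candidate
pairs) and recovery (50 seeds × 12 planted ρ = 0.6 links), 900 cells for
priming classification, and 25 seeds of the 150-cell end-to-end driver
study; these sizes make every statistical check stable while keeping a full
validation run around five minutes on one core. All randomness flows from
explicit integer seeds: the generator is a deterministic function of its
configuration, and the linking operation seeds its null sampling and
metacell grouping separately, so every table in `results/` is exactly
reproducible.

## Known limitations

* The trans-null is sampled per gene, not matched on peak accessibility or
  GC content; on real data accessibility-matched nulls would be stricter.
* Pearson linking assumes monotone, roughly linear peak-gene coupling on
  the log scale; saturating enhancers will be under-scored.
* The lag classifier needs both curves to up-cross 0.5: genes activating
  before the captured pseudotime window, or repressed genes, are
  unclassifiable by design.
* Centralities treat the network as unweighted; very different linkage
  scores on edges are invisible to the ranking (the weighted scores remain
  in the edge table).
* The generator's lineage effects are additive on a standardized latent
  scale, which makes planted divergence monotone by construction; it cannot
  probe the selection rule's behaviour under non-monotone real divergence
  beyond what the explicit non-monotone unit fixtures cover.
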