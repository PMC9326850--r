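---
title: "Robust regression scaffolding: model, parameters and design notes"
author: "ltsScaffold maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Robust regression scaffolding: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind it: the
statistical model, the assumptions it rests on, what every tunable
parameter means, what the bundled simulator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## 1. The model

Scaffolding is treated as a parameter-estimation problem. Within one
connected component of the link graph, each contig `i` has an unknown
orientation `D_i ∈ {+1, −1}` and an unknown start coordinate `β_i` on a
directed axis; the anchor contig (smallest id) is fixed at `D = +1`,
`β = 0` for identifiability.

**Orientation** is estimated first. Every link votes `d = +1` (the two
contigs read in the same direction) or `d = −1`. With `a_ij` and `b_ij`
the per-pair vote counts, the assignment minimises the Ising-type energy

    H(D) = − Σ_{edges} J_ij D_i D_j,      J_ij = (a_ij − b_ij)/2.

We sum once per unordered edge; the ordered double sum would only double
`H` and cannot change the minimiser. Minimising `H` is equivalent to a
maximum-likelihood orientation under a constant link error rate, and is
NP-complete in general, hence the heuristic search of Section 3.

**Position** estimation uses only orientation-supported links
(`d = D_i D_j`). A paired read with insert mean `μ_b` and outer-end
mapping coordinates `s_i`, `s_j` (distance from the oriented contig's
start to the fragment-side end of the read) observes

    F = μ_b + s_i − s_j          (contig i upstream)
    F = −(μ_b − s_i + s_j)       (otherwise),

and a long read with alignment starts `qs` on the read and `cs` on the
contigs observes `F = qs_j − qs_i + cs_i − cs_j`. Each `F` estimates
`β_j − β_i` with error dominated by insert-size variation, assumed
`N(0, σ_b²)` per library.

**Clustering.** The distances of one (pair, library) group are clustered
by a kernel density so that multi-modal evidence — the signature of
repeat-induced mis-mapping or insert contamination — survives as separate
observations rather than corrupting a single average. Every cluster `k`
becomes a row of the linear model

    Y_ijk = β_j − β_i + ε_k,

with `Y_ijk` the member median. By the central limit theorem for the
median, `ε_k ~ N(0, π σ_b² / (2 n_ijk))` for a cluster of `n_ijk` links,
so the row weight is `w_ijk = n_ijk / σ_b²` (the uniform `π/2` factor
cancels in the estimate); once a cluster holds more than 6 links its
member sample variance replaces `σ_b²`, letting tight or diffuse clusters
speak for themselves.

**Trimmed fitting.** Because some rows are wrong by construction, the
coordinates are estimated by weighted least trimmed squares: fit weighted
least squares on the current subset, compute residuals for *all* rows,
re-select the `(n − t)` rows with smallest absolute residuals (so a
removed row may re-enter), and stop when every selected residual is at
most `MaxError`. The normal matrix `XᵀWX` is a weighted graph Laplacian
over the free contigs and is solved sparsely. If the selected rows no
longer connect the component, the component is split and the parts
re-enter the pipeline at the orientation stage.

## 2. Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| link-count threshold | lower 10% quantile of non-zero pair counts, floor 2 | links | noise pairs (chimeras, repeats) populate the low tail; the floor keeps single chimeric reads from creating edges. For clean, uniform simulations the quantile sits inside the genuine-count distribution, so an explicit value in the 0.25–0.5 × coverage range is preferable and is what the bundled scenarios pass. |
| KDE bandwidth | `σ_b / 2` | bp | half the insert SD resolves modes one repeat unit apart at typical unit/σ ratios without shattering a clean mode. |
| peak merge distance | `2 σ_b` | bp | modes closer than twice the insert SD cannot be attributed reliably to distinct loci. |
| saddle ratio | 0.6 | — | two maxima whose saddle stays above 60% of the lower peak are one mode ("well separated" made operational). |
| minimum peak mass | 0.1 | fraction | a mode must carry ≥10% of the pair's links; smaller clumps are folded into the nearest cluster. Noise guard below the scale at which the trimming loop can adjudicate. |
| `MaxError` | 100 bp, +50 per iteration | bp | two SDs of a typical compressed observation: `2·√(π/(2·150))·500 ≈ 102.33`, rounded down; later iterations have smaller clusters, hence the schedule. |
| sample-variance switch | cluster size > 6 | links | below ~7 members the sample variance is too unstable to trust. |
| TGS pseudo-σ | MAD-SD of the pair's distances, floored at 50 bp | bp | long-read links carry no library insert model; the floor keeps near-exact alignments from collapsing the bandwidth. |
| edge filter | keep `s ≤ μ_b + 3 σ_b` (inclusive) | bp | a genuine linking fragment cannot extend past the joining edge by more than the insert span. |
| insert re-estimation | median / 1.4826·MAD, ≥100 pairs, contigs >10 kb | — | chimeric pairs are heavy-tailed; robust location/scale resist them. Below 100 pairs the nominal configuration is kept. |
| overlap tolerance | 200 bp | bp | adjacent placements overlapping more than this indicate tangled (repeat) placements and trigger branch resolution. |
| polish | identity ≥ 0.95, splice at alignment midpoint, window = overlap + 3 SE | — | conservative merge of estimated overlaps; unmatched junctions keep a 1 bp gap. |
| iterations `k` | 3 | — | links thin out as super-contigs grow; the loop also stops early when a round merges nothing. |

## 3. Numerical and algorithmic choices

* **Orientation search.** Initialisation follows the heaviest-|J| frontier
  edge from a root, setting each new vertex to `sign(J)` times its parent.
  Single best-improvement flips (ties to the smallest id) run to a local
  minimum; a Kernighan–Lin sweep (each vertex flipped at most once in
  best-marginal order, best prefix kept) escapes shallow minima, and the
  whole search restarts from up to 8 deterministic roots (by incident
  coupling mass). The result is deterministic and certified single-flip
  minimal; the suite checks it against exhaustive enumeration on 12-vertex
  instances.
* **Anchoring** is by column elimination, not a pseudo-row, so
  `β_anchor = 0` holds exactly and `XᵀWX` stays positive definite.
* **Residuals are raw bp** in the `MaxError` comparison — the bound is
  derived in bp — while the objective and fits use the weights.
* **Gap confidence intervals** use the WLS covariance scaled by the
  weighted residual mean square (degrees of freedom = selected rows −
  free parameters). With zero degrees of freedom the weight-based model
  variance is used instead and flagged; because weights are `n/σ²` while
  the median-CLT error variance is `(π/2)σ²/n`, that fallback carries the
  `π/2` factor — which is exactly what reproduces the two-SD bound of a
  single 150-link cluster.
* **Ties** everywhere (flip choice, row selection, branch resolution) are
  broken deterministically (smallest id / row index / smaller estimated
  overlap), so identical inputs give byte-identical outputs.
* **Degenerate inputs.** Single-contig components pass through; a pair
  with one distance forms one cluster; zero-coupling edges are excluded
  from the orientation tree; empty scaffold sets write valid empty files.

### Component splitting: where it can and cannot happen

The re-selection schedule removes one row per iteration, and a lone
bridging observation over a cut edge is always fitted exactly, so the
trimming loop itself can rarely disconnect a component: in the typical
case it converges on the last surviving bridge row instead. In practice
components split *upstream* — when orientation support or clustering
leaves a pair with no observations, the observation graph is checked
before fitting and the parts are re-queued. The in-loop disconnection
check is retained as a safeguard for multi-bridge conflicts.

## 4. What the simulator emulates — and what it does not

`simulateAssembly()` and friends generate: uniform-ACGT genomes with exact
planted tandem repeats; contigs as genome substrings with recorded starts
and orientations (optionally reverse-complemented, optionally with edge
regions trimmed to mimic unassembled repeat copies); paired links with
`N(μ_b, σ_b²)` inserts truncated at twice the read length, optional
short-insert contamination (default 300/30 bp) and optional relocation of
reads from a dropped repeat copy to a surviving homologous copy
(the false-cluster mechanism); and error-free long-read links from read
span geometry.

Deliberately absent: base-call errors and alignment ambiguity beyond the
explicit relocation model (the method consumes alignments; a mapper's
error profile is out of scope), chimeric reads beyond insert
contamination, GC or coverage biases, and genuine biological repeat
families (repeats are exact copies). Passing tests therefore demonstrate
the statistical machinery under the model's own assumptions, not
performance on real libraries, where mapper behaviour adds failure modes
the simulator does not generate.

Two properties of the simulator are worth knowing when reading test
numbers. First, **size-biased insert selection**: conditioning on a pair
straddling a junction tilts and, at the margins of reachability,
truncates the insert distribution, biasing linking distances — a real
phenomenon for short contigs or gaps near the insert span. The planted
scenarios are laid out so that the libraries' reach comfortably covers
the pairs being tested (the goodness-of-fit suite quantifies the residual
tilt). Second, clusters below ~7 links fall back to the library variance
for their weight, so very small false clusters are weight-limited.

## 5. Study-scenario designs

The behavioural suites run at sizes chosen to finish in minutes on one
core while keeping the statistics meaningful; each scenario's geometry is
part of the study design:

* **Planted recovery** — a 200 kb genome in 40 contigs with 200 bp gaps,
  a PE library (800 ± 80, 30×) and an MP library (5000 ± 500, 20×),
  k = 3. The suite asserts a single scaffold in planted order and
  orientation, gap RMSE < 50 bp and no gap error above 1 kb.
* **Outlier breakdown** — a 20-contig chain with 200 compressed rows of
  which 30% are false clusters offset +5000 bp. False rows carry 10-link
  clusters against 30-link true clusters: the minority-mode regime that
  mis-mapping produces. (Equal-weight outliers sharing one coherent
  offset at 30% can defeat the one-row-per-iteration greedy — a known
  limitation of greedy trimmed least squares; the trimmed objective's
  global minimiser would not break, but the pipeline does not search for
  it exhaustively.)
* **Tandem repeat** — a 16 kb genome with a 4 × 600 bp tandem block; the
  middle contig keeps copies 2–4 and a 1 kb tail, the first copy is
  unassembled, and 95% of reads from it relocate one unit downstream. A
  short-insert library (1200 ± 100, 50×) concentrates its linking mass on
  the junction, so its false cluster dominates that pair; a long-insert
  library (5000 ± 150, 12×) spans the middle contig and supplies the
  flanking-pair evidence. Multi-mode clustering plus trimming recovers
  both gaps to < 100 bp. The single-median baseline — one observation per
  pair per library, weighted `n/σ_b²` as single-observation scaffolders
  do — errs by about one repeat unit, because its poisoned row carries
  the pair's full link count. The long-insert coverage matters in both
  directions: enough of it anchors the flanking pairs for the multi-mode
  run, too much would let even the baseline outvote its poisoned row.
* **Contamination** — 20 contigs of 4 kb with 50 bp gaps and one MP
  library (6000 ± 300, 30×), 40% contaminated with 300 ± 30 inserts.
  With this geometry adjacent and skip pairs are linked without span
  truncation, so the chain carries redundant evidence and the contaminant
  modes (displaced by ≈ μ − μ_short) are trimmed. Gap estimates from the
  contaminated run are compared with the clean run gap-by-gap; the suite
  requires ≥ 90% agreement within two combined standard errors, mirroring
  the method's claim of substantially reducing — not abolishing —
  contamination-induced errors: a tight contaminant cluster that captures
  a pair's weight can still survive occasionally.

## 6. Known limitations

* The greedy trimming loop is path-dependent; adversarial outlier
  configurations (coherent common offsets at high fractions with weights
  equal to genuine rows) can lock it into a shifted frame.
* Sample-variance weighting lets a tight contaminant cluster outweigh a
  genuine diffuse one on pairs without redundant (skip-pair or
  multi-library) evidence.
* Conditional insert-size truncation biases linking distances when gaps
  or contigs approach the insert span; insert re-estimation on long
  contigs does not remove this per-pair geometry effect.
* Gap interval calibration uses normal quantiles; with few residual
  degrees of freedom the intervals run slightly narrow (the calibration
  test measures coverage within 93–97% at nominal 95%).
* Orientation search is heuristic; optimality is only certified to
  single-flip locality, with exhaustive agreement checked statistically
  on small instances.
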