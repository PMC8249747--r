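---
title: "Models and methods behind gselexchip"
author: "gselexchip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gselexchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gselexchip)
```

## The experiment being modelled

Genomic SELEX (gSELEX) identifies the binding sites of a purified
bacterial transcription factor (TF) directly on its own genome. A library
of random genomic fragments — sonication-scale segments of roughly 300 bp —
is mixed with the TF; bound fragments are recovered, amplified, and the
binding/recovery cycle is repeated several times (three to six cycles in
practice). The selected pool is then read out in one of two ways:

* **array readout**: the selected pool and the initial library are labelled
  with two dyes and co-hybridised to a tiling array of 60-bp probes spaced
  every 105 bp along the genome; the per-probe sample/reference ratio
  traces out binding peaks;
* **cloning readout**: individual selected fragments are cloned and
  sequenced, and the loci they carry are tallied.

Because a bound fragment is ~300 bp long and can start anywhere relative
to the site, the pile-up of selected fragments around a *point* binding
site spans roughly twice the fragment length, about 600 bp — five to seven
consecutive probes at 105-bp spacing. A genuine peak must therefore
elevate a *run* of consecutive probes; an isolated hot probe is noise.
This consecutive-probe criterion is the validity rule the peak caller
implements (`min_run`, default 6).

The number of regulatory targets a factor controls places it in a
hierarchy: single-target factors (1 to a few targets), local TFs (tens of
targets), global regulators (more than a hundred), and nucleoid-associated
regulators, whose published figures count on the order of a thousand
*binding sites* rather than regulated operons. A second, orthogonal label
records genome organization: *type-A* factors sit adjacent to their target
genes (commonly sharing one intergenic spacer, as `lacI` does with
`lacZYA`), while *type-B* factors lie away from their targets.

## The selection model

A TF's affinity landscape is a set of point sites with dimensionless
strengths $s_j \ge 0$ over a uniform background $b_0 > 0$
(`affinity_model()`). A fragment $f$ has bind score

$$ b_f \;=\; b_0 + \sum_{j:\, x_j \in f} s_j , $$

additive over the sites whose position falls inside the fragment. One
selection cycle multiplies every fragment weight by its bind score and
renormalises; $k$ cycles therefore enrich fragment $f_1$ relative to $f_2$
by exactly $(b_{f_1}/b_{f_2})^k$. This closed form is the backbone of the
test suite: it is checked to $10^{-9}$ relative tolerance, and it predicts
every scenario below without simulation.

Deliberately *not* modelled (no parameters for them are stated for the
emulated protocol): PCR amplification bias, fragment dropout,
sequence-dependent binding energies (no position-weight matrices), and
protein-concentration titration. Fragment lengths are truncated normal
(mean 300 bp, SD 50 bp, clipped to [100, 600]); starts are uniform on the
circle; fragments may wrap the origin, genes may not.

## The array model

Per-probe intensity is overlap-proportional fragment mass,
$\sum_f w_f\,\mathrm{ov}(f,p)/\ell_f$, computed for the selected pool
(sample channel) and the initial library (reference channel); the
reported ratio is sample/reference with a guard of $10^{-9}$ in both
numerator and denominator, times multiplicative lognormal noise
$\exp\!\big(N(0,\sigma^2)\big)$ (default $\sigma = 0.1$, a typical
two-channel array dispersion). Dye names are metadata: the package fixes
*sample over reference* semantics rather than a dye orientation.

Because both channels measure the *same* fragment set (reweighted versus
uniform), coverage fluctuations cancel in the ratio; what the simulation
retains is the geometry of enrichment around sites and the lognormal
measurement noise. Real arrays add dye bias, probe-sequence effects and
background fluorescence, none of which are modelled — passing tests show
the analysis logic is correct under the stated model, not that it would
be robust to every artefact of a physical array.

## Peak calling and target assignment

Peaks are maximal runs of probes with $\log_2$ ratio at or above
`log2_threshold` (default 1.0, conventional 2-fold; no numeric cut-off is
inherited from the emulated protocol), optionally bridging up to
`merge_gap` sub-threshold probes (default 0), kept when the run spans at
least `min_run` probes. `min_run = 6` reads the "more than six
consecutive probes" rule as *run length ≥ 6*: strict "> 6" would reject
the protocol's own ~300-bp-fragment pile-up geometry, whose zero-noise
runs measure 5–7 probes. Peaks with maximum $\log_2$ ratio of at least
twice the threshold are `high`, the rest `minor`; the published maps make
this high/minor distinction without a number, so it is explicit and
configurable here.

The peak **summit** (centre of the hottest probe) decides the genomic
context, since peak edges routinely overhang gene ends. A summit inside a
gene is an intragenic call (reported, but excluded from target counts as
presumed non-specific). A summit in an intergenic spacer nominates
targets by orientation: a **divergent** spacer carries two back-to-back
promoters and nominates both flanking units; a **tandem** spacer
nominates the unit whose 5′ end abuts it; a **convergent** spacer
nominates none. By default a divergent pair controlled from one spacer
counts as **one** regulatory locus — the bookkeeping under which a factor
binding a single bidirectional spacer that drives both flanking operons
is still a single-target factor — with per-unit counting available via
`collapse_divergent = FALSE`.

Counts between the published bands (4–9 and 51–99 targets under the
defaults) get an explicit `intermediate` label rather than forced
membership; "several" is fixed at `st_max = 3`. Nucleoid-associated
status keys on binding-*site* count (`nap_min = 500`), not regulated-unit
count. Type-A adjacency means *shares a spacer with, or is a member of, a
target unit* — no base-pair cut-off, since every published adjacent case
is immediate and the one quantified separated case lies 26 kb away.

## Scenario genome sizes

After $k$ cycles the pool mass concentrates on site-covering fragments,
so the ratio any one site can reach is capped near
$1 / (n_\mathrm{sites}\,\bar\ell / L)$, with $\bar\ell$ the mean fragment
length and $L$ the genome size. Planting many sites on a small toy genome
would therefore flatten every peak below threshold — a density artefact,
not a property of the method; on the real 4.6-Mb genome even a 20-site
local TF is sparse. The presets keep densities realistic while staying
desk-sized:

| scenario | genome | sites | library | cycles | noise SD |
|---|---|---|---|---|---|
| single-target recovery (`st_config`) | ~40 kb (20 units) | 1 × strength 9 | 10,000 | 4 | 0.1 |
| local-TF recovery (`local_config`) | ~1.2 Mb (560 units) | 20 × strength 9 | 200,000 | 4 | 0.1 |
| conditional two-state (`conditional_config`) | ~0.6 Mb | 1 vs 10 | 120,000 | 4 | 0.1 |
| weak-site decay (`weak_site_decay`) | ~0.8 Mb | 9 + 0.5 | 250,000 | 1 vs 6 | 0 |

These sizes are also what the test suite and the acceptance script run
(100 seeded runs each for the two recovery scenarios).

## The weak-site threshold: a design note

A site of strength 0.5 over background 1 has an enrichment ceiling of
1.5-fold ($\log_2 = 0.585$): no cycle count can ever lift it over a
2-fold calling threshold, so "weak non-specific binding appears early and
disappears with repeated cycles" cannot be expressed at the default
threshold — that combination of defaults is arithmetically empty. The
package therefore scans for early-stage non-specific binding at
$\log_2$ threshold **0**, i.e. any coherent enrichment above the input
library. This is principled rather than permissive: at cycle 1 the weak
locus sits mildly but coherently above the input across a full probe run,
while renormalisation keeps pure-background probes strictly *below* 0; by
cycle 6 the strong site has absorbed the pool mass and the weak locus
falls below the input level too. Appearance-then-disappearance emerges
from the multiplicative model with no extra machinery. Real peak calls
keep the 2-fold default.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is written 1-based
  inclusive and BED 0-based half-open. All writers are deterministic (no
  timestamps), so a config + seed reproduces a report bundle byte for
  byte; one seed feeds all stages in fixed order (genome, library,
  per-state noise).
* Weight renormalisation happens every cycle; pools keep
  $|\sum w - 1| < 10^{-9}$, and an all-zero-score pool is an error.
* Peak ranking breaks ties by lower genomic coordinate. Probes never wrap
  the origin (a site inside the origin-spanning spacer could split into
  two sub-threshold runs; the generator presets avoid planting there).
* Abutting or overlapping units yield no spacer; a summit in an
  intra-operon gap is treated as unit-internal, not as a spacer.
* Operon membership comes only from an explicit GFF3 `operon` attribute —
  units are taken as given annotation, never predicted.
* In the registry fixture, rows present only in the published table but
  absent from the in-text name lists (one factor) are carried with
  `in_counts = FALSE` so the summary counts reproduce the printed totals;
  alternative spellings are kept in the notes column.

## Known limitations

Single-site-per-position binding only (no cooperative or spread binding,
so footprint *widths* are not emulated, only point-site pile-ups);
features may not span the origin; no replicate arrays, dye-bias
correction or FDR machinery (peaks are deterministic given the signal);
classification of a real ~300-TF complement, and reconciliation with
curated regulon databases, are out of scope. The synthetic genome has
uniform base composition and independently placed units — it exercises
coordinate arithmetic and orientation logic, not sequence realism.
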