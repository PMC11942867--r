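---
title: "Interpreting optical genome mapping call sets in sarcomas"
author: "sarcOGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting optical genome mapping call sets in sarcomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcOGM)
```

# Scope and model

Optical genome mapping images fluorescently labeled ultra-long DNA
molecules (> 150 kbp; labels at the CTTAAG motif, 14–17 per 100 kbp) and
calls structural variants and copy-number changes against a reference map.
`sarcOGM` starts where the vendor callers stop: it takes SV junction and
CNV segment tables plus per-run QC metrics and produces an interpreted case
report for a sarcoma sample. The pipeline is a deterministic composition of
five stages — quality gating, size/VAF prioritization against a gene panel,
fusion inference from breakend orientations, chromoanagenesis detection,
and expected-alteration matching with ISCN-style reporting. Every stage is
a pure function of its inputs and configuration, so a case report is
reproducible from the call tables alone.

Internally, coordinates are 0-based half-open; chromosome names are
normalized by stripping the `chr` prefix and sorted karyotypically
(1–22, X, Y). Junctions are normalized so that intra-chromosomal breakends
satisfy `posA <= posB` and inter-chromosomal breakends are in karyotypic
order, with orientations traveling with their breakends; the two possible
encodings of one junction therefore collapse to a single record, and
normalization is idempotent. ISCN output uses band names only, so the
internal coordinate convention never leaks into reports.

# Quality gating

Three run-level metrics drive evaluability:

| metric | units | GOOD requires | rescue bands (EVALUABLE) |
|---|---|---|---|
| total DNA in molecules > 150 kbp | Gbp | > 1500 | — |
| map rate | % | > 70 | 40–50 with cov > 150×; ≥ 50 with cov > 100× |
| effective coverage | fold | > 300 | see above |

All strict inequalities; the low band is the half-open interval [40, 50).
Two reading decisions were genuinely open. First, the upper rescue band is
stated only up to a 70% map rate; we extend it upward, so a run mapping
above 70% but short of 300× coverage is EVALUABLE whenever coverage clears
100× — a better map rate cannot make a run worse, and assessable runs with
coverage near 100× occur in practice (the bundled cohort fixture contains
one at 107×). Second, GOOD requires all three recommended values jointly.
Under these rules the tier function is total (every metric triple maps to
exactly one tier) and monotone (improving any single metric never demotes
a run), which the test suite checks by perturbation.

Not-evaluable samples short-circuit `runSample()` with a QC-only report:
no variant in a failed run should reach interpretation.

# Prioritization and gene-level copy number

Prioritization keeps intra-chromosomal SVs spanning more than 500 bp
(inter-chromosomal junctions have no defined span and always pass) and CNV
segments wider than 500 bp. A VAF floor is available but off by default:
the upstream callers already apply their 5–10% detection floor, and records
lacking a VAF must not be penalized for missing metadata.

Gene-level events need numeric thresholds the source material does not fix:
we call a panel gene amplified when an overlapping segment reaches copy
number ≥ 5 and deleted at ≤ 1 (0 flagged homozygous), with simple gains
(3–4 copies) recorded on segments but not emitted as gene events. These
follow common practice in copy-number annotation and are configuration
knobs, not claims. One event per gene is reported; among qualifying
segments the largest `|cn − ploidy|` wins, ties resolve toward the more
extreme copy number and then the leftmost segment, making the call
independent of input order. Whole-chromosome loss requires loss segments
(cn ≤ 1) to cover ≥ 90% of the chromosome — whole-chromosome calls are
band-resolution statements, so demanding literal 100% coverage would be
brittle against segmentation gaps.

# Fusion inference from breakend orientations

A junction is a candidate fusion when its two breakends fall inside
distinct panel gene bodies. Orientation compatibility is decided by reading
the derivative chromosome: with the BEDPE convention (`+` = the segment
below the breakpoint enters the junction left-to-right, `-` = the segment
above enters reverse-complemented), traversal enters the junction along
breakend A in the direction of `strandA` and exits through breakend B
opposite to `strandB`. Gene A donates its promoter-side portion exactly
when the entry direction equals its transcription strand; gene B accepts as
3′ partner exactly when the exit direction equals its strand. Hence

```
A 5' -> B 3'   iff   strandA == strand(A)  and  strandB != strand(B)
B 5' -> A 3'   iff   strandB == strand(B)  and  strandA != strand(A)
```

The two cases are mutually exclusive, so each gene pair yields at most one
partner order per junction, and flipping both breakend orientations swaps
the partner order (the reciprocal product). For an adjacent opposite-strand
pair — the NAB2/STAT6 configuration — a canonical deletion junction (+/−)
is incompatible while an inversion junction (+/+ or −/−) fuses; the test
suite verifies the full rule against a brute-force enumeration of
derivative-chromosome readings on mini genes, over all 64 combinations of
gene strands and breakend orientations.

Exon and reading-frame awareness are deliberately out of scope: breakpoints
resolve to gene bodies. When a breakend lies in overlapping genes, all
candidate pairs are emitted with the smaller (more specific) gene ranked
first — no principled tie rule exists at gene-body resolution. Junctions
touching a single panel gene are reported separately as gene
rearrangements, matching the expected-alteration grammar (for example a
PHF1 rearrangement).

# Chromoanagenesis

**Chromoplexy** is operationalized on a breakend graph: nodes are
breakends, each junction contributes an edge between its two ends, and
adjacency edges link breakends of different junctions on the same
chromosome when they are less than `maxGap` apart or when a deletion spans
the interval between them (a deletion bridge, any size). The default gap is
five labels' worth of sequence at the canonical density, 5 × 100000 / 15 ≈
33 kb; with an actual label map, `labelGap()` converts label counts to
base pairs locally. Chains are the connected clusters of this graph whose
junctions span at least three chromosomes. When every breakend has at most
one adjacency, clusters are exactly the alternating junction/adjacency
paths and cycles; when a breakend could link to several partners we keep
the whole cluster as one chain rather than impose an arbitrary
decomposition. Chains are breakend-disjoint by construction, and the
implementation (igraph components) is tested for equality against an
independent transitive-closure enumeration on random instances of up to 10
junctions. Chains may not share junctions; whether they ever should is
unresolvable at this resolution, and disjointness is the conservative
choice. Note that two chained translocations t(1;2)+t(2;3) already span
three chromosomes and therefore qualify — the chromosome count, not the
junction count, carries the definition.

**Chromothripsis** detection slides a 50 Mb window at 1 Mb stride along
each chromosome. "Interspersed and uniform in the affected region" is not
operationalized in the source material; this module's definition is: the
*affected region* of a window is the extent of copy-number segmentation
intersecting it (chromothripsis requires CNVs *coexisting* with the
rearrangements, so the CN-variable span is the region under judgment —
and sporadic breakpoints elsewhere in the window are unrelated activity
that must not veto it). A window is flagged when, over that span, (a) more
than seven junctions have at least one breakend inside — each junction
counted once, in-span ends of inter-chromosomal junctions included,
"more than seven" strict; (b) the segments carry at least two distinct
copy-number states; (c) neither half of the span holds more than 80% of the
breakpoints; and (d) a one-sample Kolmogorov–Smirnov test does not reject
uniformity of breakpoint positions over the span at α = 0.01. Overlapping
flagged windows merge into maximal regions, whose statistics are recomputed
over the merged span; re-running the merge is a fixed point, and raising
the junction threshold never increases the region count. The reported
region carries its evidence (junction count, CN states, KS statistic,
interspersion flag) so that the conventional manual review step can audit
a deterministic call rather than replace it.

α = 0.01 for the KS test trades a ~1% false rejection of genuinely uniform
breakpoint sets against power to reject clustered ones; with the 80%
interspersion cap it rejects configurations where the junctions pile into
a fraction of a copy-number-affected span. Case classification is then the
obvious enum: chains only → CHROMOPLEXY, regions only → CHROMOTHRIPSIS,
both → BOTH, neither → NONE.

# The synthetic cohort generator

The generator exists so that every detector can be scored against known
truth. `makeToyGenome()` builds a 16-chromosome, 660 Mb genome carrying
analogs of all genes the interpretation rules reference, placed on
synthetic cytobands named after their real counterparts (the MDM2-analog on
12q15, an adjacent opposite-strand NAB2/STAT6 pair on 12q13.3, the
MDM2/CDK4/HMGA2 cluster on one arm, fusion partners across chromosomes).
Label positions are drawn per seed with per-chromosome density kept inside
14–17 per 100 kbp. Scenarios:

* `QUIET` — background junctions only: positions uniform, sizes log-uniform
  in [500 bp, 1 Mbp], VAF uniform in [0.05, 0.5] (respecting the platform's
  detection floor; the floor value itself is the only constraint the
  source material provides, so the rest of the noise model is a modeling
  choice).
* `SIMPLE_FUSION` — one two-gene junction whose orientations are computed
  from the partners' strands (gene strand at the 5′ breakend, flipped
  strand at the 3′ breakend), or deliberately incompatible deletion-type
  orientations for negative controls.
* `MDM2_AMPLICON_CT` — 20 junctions with breakpoints uniform over a 30 Mb
  span of the 12q-like arm, copy-number oscillating 2↔8 in ten segments,
  plus a cn = 12 amplicon over the MDM2-analog.
* `CHROMOPLEXY_CHAIN` — a closed chain across k ≥ 3 chromosomes with
  same-chromosome gaps drawn below `maxGap`, optionally replacing gaps
  with long deletion-bridged transitions.
* `MIXED` — superposition of the above.

Each case also draws QC metrics from a per-tissue two-component mixture:
an assessable component (truncated normals around typical good-run values,
re-drawn until the metrics classify GOOD/EVALUABLE) weighted by the
tissue's evaluability probability — adipocytic 12/21, non-adipocytic 11/15,
bone 2/6, uncertain 5/7, small round cell 3/4 — and a degraded component
otherwise. Expected evaluability matches the group rates by construction;
only the rates, not the metric distributions, are asserted anywhere.

What the generator does **not** emulate: molecule-level noise and label
resolution (breakpoints are exact), mapping artifacts and reference gaps,
subclonal heterogeneity beyond a scalar VAF, germline polymorphism, and the
two-caller redundancy of the vendor stack (pipeline-tier flags are carried
as data, not re-derived). Passing recovery tests therefore demonstrates
that the detectors implement their definitions correctly on clean calls —
not that those definitions are robust to caller-specific artifacts on real
samples.

# Bundled fixtures

A 33-case reference cohort ships as a plain TSV: per case the subtype, the
expected-alteration rule in the closed grammar (`fusion(a,b)`,
`gene_rearrangement(g)`, `amplification(g)`, `cnv_sv_any`), the alteration
category, the detected flag with its pipeline tier, and the run's DNA yield
and coverage. Per-case raw call sets are not available at this granularity,
so `cohortFixtureReports()` synthesizes the minimal event objects each
row implies and replays them through `matchExpected()` — exercising the
grammar and tier bookkeeping, not the detectors. Map rates are not part of
the fixture, so replayed reports record the tier as EVALUABLE rather than
guessing GOOD. A case whose expectation was an unknown rearrangement is
encoded as `cnv_sv_any` with category `fusion` (its defining fusion emerged
on review). Cohort-level chromoanagenesis frequencies cannot be recomputed
from the fixture for the same reason; detector validity is instead
established by the simulation properties above. The gene panel and
cytoband tables bundled under `inst/extdata/` are synthetic stand-ins on
the toy genome (marked `synthetic` in their filenames); they contain every
gene the rules reference but are not a reference annotation.

# Numerical choices and degenerate inputs

* Band assignment is half-open: a position on a band start belongs to that
  band; positions beyond the table raise an error rather than guessing.
* Empty call sets flow through every stage and yield a valid zero-event
  report; an empty cohort manifest is an error.
* KS tests on breakpoint positions suppress the tie warning (integer
  positions can collide); the decision uses the p-value, the report stores
  the statistic.
* `simulateQC` rejection-samples within mixture components; acceptance
  regions are wide, so the loops terminate after a handful of draws.
* All simulation entry points take an explicit seed and restore the
  caller's RNG state, so library use never perturbs user randomness.

# Validation sizes

The shipped checks run the chromoplexy/oracle comparison on 200 random
instances of up to 10 junctions, detector recovery on 200 positive and 200
quiet simulated cases (observed: sensitivity ≳ 0.95 at a false-positive
rate of 0), chain recovery for 3–6-chromosome chains on 200 cases, QC
calibration at n = 1000 per tissue, and the fusion enumeration over all
orientation/strand combinations. These sizes give binomial standard errors
below 2 percentage points on the recovery estimates while keeping the whole
suite under a minute of compute; they are the package's validation
configuration, not a statement about the limits of the method.

# Limitations

Interpretation is gene-body-resolution: no exon/frame checks, no RNA-level
confirmation. LOH-region calling is a stub (`detection_tier` bookkeeping
accepts De-Novo-only flags, but no allele-resolved analysis is performed).
The ISCN surface covers the subset the reports need — t, inv, −N, amp —
not full karyotype strings. The chromothripsis criteria are a deliberate
operationalization of a verbal definition; regions flagged here identify
candidates with auditable evidence, they do not adjudicate mechanism.
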