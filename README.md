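# sarcOGM

Interpretation of optical genome mapping (OGM) call sets in soft-tissue and
bone sarcomas.

OGM resolves structural variants (SVs, 500 bp–1 Mbp), copy-number variants
and complex rearrangements genome-wide from labeled ultra-high-molecular-
weight DNA, at variant allele frequencies down to 5–10%. In sarcoma
diagnostics the calls themselves are only half the problem: a case must be
gated on run quality, the calls prioritized against a panel of
sarcoma-relevant genes, candidate gene fusions inferred from breakend
orientations, catastrophic rearrangement patterns (chromoplexy,
chromothripsis) recognized, and the result matched against the alteration
expected for the histological subtype and written in ISCN-style
nomenclature. `sarcOGM` implements that interpretation layer as a tested,
deterministic pipeline for cytogeneticists and method developers, together
with a scenario-structured cohort simulator so every stage can be validated
without access to patient data.

## The rules at the core

* **Run quality.** A run is *good* when total DNA (molecules > 150 kbp)
  exceeds 1500 Gbp, map rate exceeds 70% and effective coverage exceeds
  300×. A run short of those targets is still *evaluable* when the map rate
  is 40–50% with coverage > 150×, or ≥ 50% with coverage > 100×; anything
  else is not evaluable.
* **Prioritization.** SVs spanning > 500 bp (inter-chromosomal junctions
  always) and CNVs > 500 bp, intersected with the gene panel. Gene
  amplification at copy number ≥ 5, deletion at ≤ 1 (0 flagged homozygous),
  whole-chromosome loss when loss segments cover ≥ 90% of the chromosome.
* **Fusion orientation.** With BEDPE breakend orientations, a junction
  fuses gene *A* (5′) to gene *B* (3′) iff `strand(breakendA) == strand(A)`
  and `strand(breakendB) != strand(B)` — i.e. the derivative chromosome
  reads 5′→3′ from *A*'s promoter through the junction into *B*. For an
  adjacent opposite-strand pair such as *NAB2*/*STAT6* this is exactly why
  a plain deletion cannot produce the fusion but a small inversion can.
* **Chromoplexy.** Chained rearrangements across ≥ 3 chromosomes, with
  same-chromosome breakends linked when less than five labels apart
  (≈ 33 kb at 15 labels/100 kbp) or when a deletion bridges the gap.
* **Chromothripsis.** A region where copy-number variation coexists with
  more than seven rearrangements within a 50 Mb window, the breakpoints
  interspersed (neither half of the affected span holds > 80% of them) and
  compatible with a uniform distribution (one-sample KS test).

## Worked example

Simulate an MDM2-amplicon chromothripsis case on the bundled toy genome and
interpret it end to end:

```r
library(sarcOGM)
g  <- makeToyGenome(seed = 1)
cs <- simulateCase(g, simScenario("MDM2_AMPLICON_CT"), seed = 3)
rep <- runSample(cs$svs, cs$cnvs,
                 list(total_dna_gbp = 1514, map_rate_pct = 74,
                      effective_coverage = 339),
                 g@genes, g@cytobands, toyChromSizes(),
                 expectedRule = alterationRule("amplification", "MDM2"),
                 caseId = "case35", subtype = "Dedifferentiated Liposarcoma")
rep
```

```
CaseReport case35 ( Dedifferentiated Liposarcoma )
  QC tier:         GOOD
  expected rule:   amplification(MDM2)
  detected:       TRUE [RVA]
  chromoanagenesis: CHROMOTHRIPSIS
  ISCN:            amp(CDK4)(12q14.1), amp(MDM2)(12q15)
```

The run passes the recommended quality thresholds (GOOD); the expected
*MDM2* amplification is found (copy number 12 over the MDM2-analog locus on
12q15, alongside a CDK4-analog amplification); and the rearrangement
cluster on the 12q-like arm — 22 junctions over 30 Mb with copy-number
states oscillating among 2, 8 and 12 — is classified as chromothripsis, the
pattern characteristic of dedifferentiated liposarcomas. `caseEvents(rep)`
exposes the full evidence tables (fusions, gene CNV events, chains,
regions) and `writeCaseReportJSON(rep, "report.json")` serializes them.

A bundled 33-case reference cohort (`cohortFixture()`), tissue-group
evaluability counts (`evaluabilityFixture()`) and three diagnosis-refinement
worked examples (`reclassifiedCasesFixture()`) let the reporting layer be
exercised against known cohort-level results; `cohortFixtureReports()`
replays them through the matching engine.

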