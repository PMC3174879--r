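---
title: "In silico cDNA-AFLP and the imprinted-gene screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico cDNA-AFLP and the imprinted-gene screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpimprint)
```

# The problem

Genomic imprinting — parent-of-origin-dependent monoallelic expression — is
concentrated, in flowering plants, in the triploid endosperm of the seed.
A cDNA-AFLP screen can detect it without microarrays or sequencing: cDNA
from reciprocal F1 hybrids is digested with two restriction enzymes,
adapter-ligated, selectively amplified, and sized on a capillary analyser.
A transcript-derived fragment (TDF) that appears only when a given accession
is the *mother* is a candidate maternally expressed gene (MEG). The
informatic bottleneck is identifying *which gene* produced a TDF, given only
its size and the selective nucleotides of the primers that amplified it.
`aflpimprint` implements that identification engine together with the
surrounding screening logic: a parent-of-origin caller, an
endosperm-enrichment ranker, a pyrosequencing allele-fraction summarizer,
and a DMR finder for candidate imprinting control regions.

# The digestion and amplification model

## Fragment geometry

The default enzyme pair is BstYI (recognition `RGATCY`, cut after the `R`)
and MseI (`TTAA`, cut after the first `T`); both sites are palindromic under
IUPAC complementation (`R`↔`Y`), so scanning the sense strand finds every
duplex site — a property asserted at package load. Degenerate codes in the
recognition sequence are expanded during matching (via
`Biostrings::matchPattern`); an `N` in the *transcript* deliberately matches
nothing, so masked sequence can never produce phantom fragments.

Cut positions from both enzymes jointly partition the transcript. A
candidate fragment is an interval between *consecutive* cuts whose 5'
boundary is a BstYI cut and whose 3' boundary is an MseI cut — only such
fragments receive both adapters and amplify exponentially. Same-enzyme
intervals are excluded by default (`keep_same_enzyme = TRUE` reports them
for diagnostics). Each fragment therefore begins with the remnant
`GATC[C/T]` and ends with the remnant `T`; products shorter than 6 nt
(remnants plus one internal base) are discarded. The wet protocol isolates
only the poly-A-proximal fragment, so `mode = "last"` (the default for
index building) keeps the fragment with maximal start.

## Selective nucleotides

The second-round primers carry the Y-position base (`C` or `T`) plus up to
two selective nucleotides on each side. On the BstYI side the context is
read on the sense strand immediately 3' of the `GATCY` remnant. On the MseI
side the primer anneals to the opposite strand, so the context is the
*reverse complement* of the sense bases immediately 5' of the terminal
remnant `T`. The source protocol never states this orientation convention;
we derived it from primer-annealing geometry and verify it in the test
suite with a full-PCR oracle that reconstructs the literal amplicon
(BstYI-primer tail + fragment + reverse complement of the MseI-primer tail)
and checks that both full selective primers sit at the amplicon ends. The
protocol's two amplification rounds (+1 then +2 selective bases) collapse
to a single filter on the final-round primers, since round-1 selectivity is
a strict prefix of round-2 — the fragment set is identical.

## Predicted capillary size

The predicted migrated size is the cut-to-cut length plus a constant
correction. The default correction of 26 comes from the printed primer
geometry: the 18-nt BstYI primer overlaps 7 fragment bases (`GATC`+Y+NN)
and extends 11 nt beyond the 5' cut; the 18-nt MseI primer overlaps 3
(remnant complement + NN) and extends 15 nt beyond the 3' cut. The adapter
sequences as printed in the source protocol do not form clean complementary
duplexes, so the correction is derived from primer lengths rather than
adapter reconstruction, and `size_model()` makes it configurable: capillary
mobility and dye shifts make the effective offset assay-specific in
practice.

# TDF-to-gene matching

`build_index()` digests every transcript under one configuration and keys
the fragments by primer combination. `match_tdf()` keeps candidates whose
predicted size deviates from the observed size by at most `tolerance`
(default 1.0 bp — the stringent setting of the original screen — read as an
*inclusive* bound; sizes stay fractional because capillary sizing is
fractional and the original tool's rounding behaviour is unstated).
Isoforms are collapsed to genes before the status call (`unique` /
`ambiguous` / `unmatched`), reporting the minimal deviation per gene for
determinism; the nearest out-of-tolerance candidates are reported as near
misses. Gene ids derive from transcript ids by stripping a trailing
`.<number>` isoform suffix, overridable with an explicit map. Two
properties pin the semantics: candidate sets are nested in tolerance
(status can only move unmatched → unique → ambiguous as tolerance grows),
and adding a duplicate isoform of an indexed gene never changes any status.

# Parent-of-origin calling

The screen design has, per timepoint, both parental selfs and both
reciprocal F1s. A TDF is *polymorphic* when present in exactly one
accession's self, consistently across timepoints — the signature of a SNP
disrupting the other accession's restriction site. Presence calls come from
capillary size bins (±0.5 bp half-width, centers seeded from parental-self
peaks, nearest center winning on overlap; `assign_bins()`).

For a polymorphic TDF with carrier accession X, each timepoint is
classified from the reciprocal F1 pair: maternal-supporting (present only
when X is the mother), paternal-supporting (mirror), biallelic (present in
both), silent (absent in both), or uninformative (any required sample
missing — missing data is never treated as contradiction). The call is
`maternal`/`paternal` when at least `min_stages` (default 2, "at least two
of the stages sampled") timepoints support one direction and none supports
the opposite; any opposed support, or a biallelic timepoint alongside
sub-threshold support, gives `not_uniparental`; otherwise
`insufficient_evidence`. These rules make the category assignment total and
exclusive, and the label symmetry (swapping accession names changes the
carrier, never the maternal/paternal direction) is tested as a property.

# Endosperm-enrichment ranking

Maternal expression detected in whole siliques can come from the (entirely
maternal, diploid) seed coat rather than from imprinting in the endosperm.
The ranker therefore works from per-tissue expression means (seed coat,
embryo, and the peripheral/micropylar/chalazal endosperm fractions).
Records are first partitioned: no usable probe → excluded; not present in
seed → set aside; endosperm fractions all below the presence floor with
seed coat above it → seed-coat-only; best endosperm fraction not exceeding
seed coat → dropped (ties excluded, since the screen selects genes with
*higher* endosperm expression). The remaining endosperm-dominant genes are
ranked by the absolute difference hEF − SC between the highest-expressing
endosperm fraction and the seed coat, with the ratio hEF / SC reported as
the complementary relative key (infinite when SC = 0; such genes still rank
by absolute difference). The embryo column never influences the result — a
permutation test asserts this. Presence is an *input* (array absence calls
from the source dataset are not recomputable), defaulting to a numeric
floor of 0 when no call column is supplied.

# Pyrosequencing summaries

Allele-specific pyrosequencing yields per-allele signal at a transcribed
SNP; the maternal fraction is `100 * m / (m + p)` (undefined and reported
missing when both signals are zero). Gene summaries average the two
reciprocal directions; classification thresholds are explicit configuration
because the published labels are interpretive: defaults call ≥ 90% mean
maternal *binary maternal*, 70–90% *preferential maternal*, 30–70%
*biallelic*, mirrored below. These defaults reproduce the qualitative
labels of the standard control genes (a binary MEG near 95%, a preferential
PEG near 20%, a biallelic control near 46%) from their printed
per-direction values.

# DMR finding

The search region for candidate imprinting control regions is the
intergenic neighborhood: from the end of the nearest gene body on the left
to the start of the nearest on the right, including the candidate's own
body (chromosome ends where no neighbor exists; overlapping neighbors
truncate with a warning). Within the region, a cytosine is differential
when |pct~B~ − pct~A~| ≥ `min_diff`; differential cytosines chain while
consecutive ones are ≤ `max_gap` apart; chains with ≥ `min_count` members
are DMRs. Reported counts distinguish all cytosines in the interval from
differential and from hypermethylated-in-B ones. "Downstream" means 3' of
the gene body on the gene's strand, distance measured from the gene-body
boundary to the nearest DMR edge. Cytosine context (CpG/CHG/CHH) is
pass-through metadata: the source analysis aggregated all cytosines.

The source describes no thresholds; the defaults — `min_diff` 20 percentage
points, `min_count` 5 cytosines, `max_gap` 250 bp — are conventional
bisulfite-DMR heuristics, and every report echoes them in its header so
results are self-describing. The published per-locus DMR coordinates depend
on an external methylation dataset and unstated thresholds, so they are a
calibration exercise, not a numeric oracle; correctness is instead
established by brute-force chain enumeration on small inputs and by planted
recovery (below).

# What the synthetic data emulates — and what it does not

`simulate_transcriptome()` builds each transcript as 5' filler + `RGATCY` +
spacer + `TTAA` + 3' filler + poly-A, with all filler drawn from a T-free
alphabet: without `T` neither recognition sequence can occur in the filler
or across any junction, so the planted sites are provably the only ones
(a defensive post-scan re-digests every transcript and stops on any
violation). Accession B copies A, then a configured fraction of genes get a
single-base change destroying the BstYI (`GATC`→`GGTC`) or MseI
(`TTAA`→`TCAA`) site — the polymorphism class the screen detects.
`simulate_allele_table()` translates the truth into presence/absence over
the 4-samples × 3-timepoints design with configurable maternal fraction,
expressed-timepoint count and dropout; `simulate_methylation()` plants
effect-size clusters over bounded background noise. All generators are
byte-deterministic under a fixed seed.

The generators emulate the *geometry* of the screen, not its biology: real
transcriptomes have T-rich sequence, multiple fragments per transcript,
partial digestion, PCR competition, sizing error beyond the binning model,
and expression noise; real polymorphisms are not always single
site-destroying SNPs; methylation tracks have read-depth structure and
context dependence. Passing the recovery suites therefore shows the
*algorithms* are correct against their definitions, not that the screen's
published gene counts would be reproduced on real data — those counts
depend on the original capillary electropherograms and mid-2000s transcript
sets and are out of reach by construction.

# Validation scale and numerical choices

The validation suites run at desk scale: gene self-recovery on a 200-gene
synthetic transcriptome, digestion-vs-oracle agreement on 100 random
transcripts (lengths 80–1200), parent-of-origin recovery on 150–200 genes
across 3 timepoints, and DMR recovery with 3 planted regions (effect 40
points, background noise 5, detection threshold 20) over ~320 cytosines —
sizes chosen to exercise key collisions and chaining edge cases while
keeping the whole suite fast. Worked-table reproductions use the packaged
printed inputs; recomputed derived columns agree within ±0.02 (the printed
inputs are rounded to 2 decimals, and several printed derived cells differ
from exact recomputation by 0.01). Two printed pyrosequencing means are
arithmetically inconsistent with their printed per-direction values
(evidently computed from unrounded replicates) and are excluded as numeric
oracles; the fixture flags them.

Other deliberate choices: coordinates are 0-based half-open internally and
1-based closed at GFF3 boundaries; matching deviation uses an inclusive
bound; within-gene isoform ties break by minimal deviation; hEF ties across
endosperm fractions break by column order (peripheral, micropylar,
chalazal), which affects only the reported fraction name, never the value;
enzymes labelled "frequent" or "rare" cutters carry no behavioural meaning
here. Non-palindromic enzymes are rejected with a clear error rather than
silently mishandled; methylation-sensitive digestion and electropherogram
simulation are out of scope.
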