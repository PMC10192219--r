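---
title: "Profiling peptidyl-tRNA drop-off from mass lists: models and methods"
author: "pepTRNAprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling peptidyl-tRNA drop-off from mass lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepTRNAprof)
```

## The biological problem

During the first rounds of translation elongation in bacteria, peptidyl-tRNAs
(pep-tRNAs) frequently dissociate from the ribosome ("drop-off") and are
recycled by peptidyl-tRNA hydrolase (PTH). In a temperature-sensitive PTH
strain, dropped-off pep-tRNAs accumulate and their nascent peptides can be
released and measured by LC/MS as a deconvoluted list of neutral
monoisotopic masses. Each observed mass is then interpreted against the
N-terminal peptide repertoire of the organism's ORFs: a mass matching an
N-terminal prefix (optionally lacking the initiator Met) evidences a cognate
drop-off event at the codon of the peptide's C-terminal residue; a mass
matching a prefix with exactly one amino-acid substitution evidences a
miscoding event, typed by the substitution's distance from the drop-off site
(C0X at the site itself, C-1X one codon upstream, and so on).

`pepTRNAprof` implements this computation end to end: mass arithmetic for
modified nascent peptides and peptidyl-adenosine species, reference-database
construction, ppm-tolerance annotation with class precedence, drop-off
quantification, codon-level statistics at drop-off sites, and a seeded
synthetic-data generator so every stage is testable without external data.

## Mass model

All masses are neutral and monoisotopic. A peptide's mass is the sum of its
residue masses plus terminal chemistry:

* free acid: residues + H2O;
* peptidyl-adenosine ester (the nuclease-P1/phosphatase digestion product of
  an acylated tRNA): residues + adenosine, i.e. the free acid − H2O +
  adenosine;
* free acid with one C-terminal 18O (hydrolysis of the ester in
  18O-labelled water): free acid + 2.004246 Da, a nominal +2 Da shift.

N-terminal acetylation (+42.010565) or formylation (+27.994915) and Met
oxidation (+15.994915 per site) are additive deltas. Cys is always carried
as carbamidomethyl-Cys because the workflow alkylates thiols with
iodoacetamide before analysis; an unmodified Cys is deliberately not
representable. Ions are singly protonated by default
(m/z = (M + z·1.0072765)/z); multiply charged ions are supported but never
inferred.

Two residue-mass tables ship with the package. The default `"paper"` table
reproduces the residue masses printed with the original profiling method, so
reference databases match the published ones bit for bit. The `"standard"`
table is summed from atomic compositions. The printed values sit 1e-4 to
3e-4 Da below the atomic sums (about 1-2 ppm; e.g. carbamidomethyl-Cys
160.03041 printed vs 160.03065 computed); the origin of the offset is not
documented, so both tables are provided and the discrepancy is surfaced
rather than hidden. Both tables reproduce the published anchor m/z values
(Ac-Ala-Ado 381.15, Ac-Met-Ala-Ado 512.19, f-Met-Ado 427.14) at 2-decimal
rounding, and the test suite checks every residue against an independent
atomic-composition oracle within 5e-4 Da.

```{r anchors}
tb <- residueMassTable()
sp <- peptideSpecies("MA", "acetyl", "adenosine_ester")
round(mzFromNeutral(neutralMass(sp, tb), 1, tb), 2)
```

## Reference databases

`buildCognateDb()` enumerates, for every valid ORF (in-frame CDS with an
ATG/GTG/TTG start translated as initiator Met, a terminal stop and no
internal stop), the N-terminal prefixes of each length in a configurable
range. The profiling default is 3-14 residues; the search-engine FASTA
export defaults to the overlapping 4-10 and 10-16 ranges used for MS/MS
database searches (a published description of the isolated pep-tRNA search
also mentions 4-17; the ranges are configurable and the export default
follows the database description). When the second residue is small
(G, A, S, T, C, P, V, N, D, L, I), methionine aminopeptidase removes the
initiator Met, so Met-trimmed counterparts are added. Drop-off positions are
1-based codon positions with the initiator as codon 1: a retained-Met
peptide of length L drops off at codon L, a trimmed one at codon L+1 (a
trimmed 7-mer covers codons 2-8).

`buildSubstitutionDb()` expands each cognate prefix into single amino-acid
substitution variants at a configurable set of C-terminal offsets (default:
every position). Substitutions with zero mass change (Ile/Leu) are excluded
because mass-only profiling cannot evidence them; the sequence-level FASTA
export keeps all residues and instead supports `"X"` wildcards at chosen
offsets for search engines. Trimming eligibility of a substitution variant
is decided on the cognate second residue, because Met excision acts
co-translationally on the true nascent sequence before any later
miscoding is observable.

## Matching and classification

Observed features (neutral mass, or m/z with charge assumed 1 unless given)
are first filtered against a control list measured at t = 0: any sample mass
within tolerance of a control mass is chemical noise and removed. Matching
then proceeds on a sorted mass index with binary-search windows,
contractually equivalent to an all-pairs scan (and tested against one). The
tolerance is inclusive, |dppm| <= 5 by default, applied on neutral mass.

Each peak receives exactly one label. Cognate precedence comes first: a peak
matching any cognate reference is cognate even if substitution references
also match (the triage order of the profiling workflow). Otherwise the best
substitution candidate - smallest |dppm|, ties broken by gene id then
sequence, deterministically - sets the class via its offset. Peaks are
counted once regardless of candidate multiplicity; the full ranked candidate
list is retained alongside.

A caveat that matters for interpreting per-offset labels: with a full
substitution database, distinct reference masses are dense on the mass axis
(hundreds of thousands of values over ~1300 Da), and genuinely
near-degenerate compositions exist (Asn vs Gly-Gly differ by 0.0004 Da; the
same residue swap at two different positions of one peptide gives exactly
equal masses). Inside a 5 ppm window several references with different
offsets therefore co-occur routinely, so mass alone identifies *that* a
single substitution occurred far more reliably than *where*. This mirrors
the original study, where the C0X..C-3X typing of individual pep-tRNAs came
from CID sequencing rather than from bulk mass profiling. Consequently the
package's recovery checks validate the cognate tier, the overall
single-substitution share, and the positional window of C0X detections -
all robust - rather than per-offset label accuracy, which is intrinsically
limited.

## Quantification

* `relToReference()` normalises species areas against f-Met-Ado, whose
  steady-state level is unaffected by brief PTH inactivation.
* `timecourseRelative()` implements the two published conventions:
  amino-acyl species are reference-normalised then divided by their t = 0
  value; dipeptidyl species are reported reference-normalised per timepoint.
* `summedAbundance()` totals normalised series per timepoint, optionally as
  percent of a baseline timepoint (default t = 0; the published percentile
  scaling is ambiguous between baselines, so the baseline is configurable
  and raw sums are always available).
* `dropoffFrequency()` is the tylosin ratio: relative abundance without
  drug over relative abundance at saturating tylosin (0.1 mg/ml), the
  maximum dissociable pool. Values above 100% are possible with noisy
  inputs and are flagged, never clipped.
* `dropoffRate()` is the k-mer fraction n_k / (n_k + n_(k+1)) of
  consecutive n-mer amounts, the published 4-mer/5-mer reporter statistic.
* `fitCalibration()` / `absoluteQuantify()` implement external-standard
  absolute quantification by ordinary least squares in log10-log10 space;
  the slope is not constrained to 1, and extrapolation beyond the fitted
  range is flagged.

## Codon statistics

Codon tallies at drop-off sites (and at the 3'-adjacent codon, the stalled
A-site of a cognate pep-tRNA) are computed per class over the 61 sense
codons. Transcriptome-side usage is TPM-weighted: codon counts in a
positional window (default codons 5-17) weighted by each mRNA's TPM share,
invariant to global TPM rescaling. `gcGroup()` classifies codons by their
number of G/C bases. `codonTallyR2()` reports the squared Pearson
correlation of two frequency vectors (the standard reading of "coefficient
of determination" for two frequency sets, which the source material does
not define further), with named-codon exclusion. `usageDeviation()`
computes per-codon window-vs-total usage ratios and their standard
deviation sigma (windows 2-8 vs 9-15 in the published comparison).
`orfGrouping()` partitions top-TPM ORFs (default top 20%) into early
drop-off (codons 5-6), later-only, and undetected groups.

Codon-anticodon mismatch counting pairs codon position i with anticodon
position 4-i and counts non-Watson-Crick pairs (0 = cognate, 1 =
near-cognate, >=2 = multiple). Wobble handling is off by default - the
source material does not state its rule, and strict Watson-Crick is the
conservative choice - with a documented option accepting G:U/U:G at codon
position 3 for sensitivity analysis.

## The synthetic-data generator

`simConfig()` fixes the emulated study conditions; the defaults are the
conditions under which the package's recovery claims are made:

* 200 ORFs of 30-60 codons; codons 2-8 drawn from an AU-enriched
  distribution (weight (1 + 1.5)^(A/U count)) to emulate the early
  AU-richness of bacterial ORFs, uniform sense-codon usage elsewhere;
  log-normal TPM (meanlog 1, sdlog 1) scaled to one million.
* 5,000 features at t = 30, of which 60% are unassignable decoys - the
  approximate share of unmatched peaks in real profiling data - planted in
  both the t = 0 control and the sample so noise subtraction removes them.
* 20.8% of true peptides carry a single substitution (the published
  non-cognate share), with offsets split 286:10:4:4 across C0X..C-3X, the
  published class counts.
* Non-cognate drop-off positions concentrated at codons 5-9 (about 98% of
  planted C0X events, echoing the published ">95% between the fifth and
  ninth positions"); cognate positions spread over codons 3-15.
* Gaussian mass error of 1 ppm; matching tolerance 5 ppm.

Trimming follows the MAP rule deterministically. True masses equal the mass
model's values exactly before noise. To keep planted labels unambiguous for
a 5 ppm matcher, substituted-peptide masses are re-drawn if they fall within
twice the tolerance of any cognate reference mass, and decoy masses are
drawn uniformly over the reference mass range excluding twice-tolerance
windows around cognate masses. (Excluding decoys around *substitution*
masses as well is infeasible by construction - those windows tile
essentially the whole axis - and unnecessary, because decoys are removed as
chemical noise before matching.)

What the generator does not emulate: retention-time structure, isotope
envelopes and charge deconvolution errors, intensity-dependent detection,
truncated or multiply substituted peptides, and ribosome kinetics. Passing
recovery tests therefore demonstrate the correctness of the annotation
arithmetic under the stated error model, not performance on raw
instrument data.

```{r sim, eval = FALSE}
cfg <- simConfig(seed = 42)
orfs <- simulateOrfeome(cfg)
sim <- simulateDropoffPeaks(orfs, cfg)
out <- runProfile(orfs, sim$peaks, sim$control, tolPpm = cfg$tolPpm)
evaluateRecovery(sim$truth, out$result)
```

## Numerical choices and degenerate inputs

* Tolerance boundaries are inclusive; ppm errors are signed,
  (observed − reference)/reference × 1e6.
* Candidate ranking is |dppm|, then gene id, then sequence - total and
  deterministic, so identical inputs give byte-identical outputs.
* Empty controls are a warned no-op; empty databases or peak lists yield
  empty results rather than errors wherever a partition remains definable.
* Malformed ORF records are skipped with a summarising warning, never
  silently dropped.
* Zero baselines in time courses yield NA with a warning; both-zero inputs
  to the drop-off rate are an error because the statistic is undefined.
* Calibration round-trips are exact for noiseless two-point fits; a small
  relative slack (1e-9) keeps boundary points from being flagged as
  extrapolation.

## Problem sizes used by the shipped checks

The test suite exercises small ORF sets (8-60 ORFs) for unit and property
tests and one full-scale run of the default study conditions (200 ORFs,
5,000 peaks, a substitution database of ~600,000 entries) for end-to-end
recovery; the complete suite runs in well under a minute on one CPU. These
sizes were chosen so that the closed-form database-size checks, the
all-pairs oracle comparison (kept at or below 10^4 database entries) and
the binomial recovery interval all have enough statistical resolution while
remaining quick to rerun.

## Limitations

Mass-only annotation cannot distinguish Ile from Leu, cannot localise a
substitution within a near-degenerate candidate set (see above), and
attributes a peak to a single best reference when several genes share an
N-terminal prefix. MS/MS-scale evidence enters only through
`importIdentifications()`, which applies the published pass-through filters
(|dppm| < 5, score > 30, expectation < 0.05) and disambiguation policy
(higher score, cognate preference, higher TPM, otherwise excluded) to
externally produced identification tables; the package does not score
spectra itself.
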