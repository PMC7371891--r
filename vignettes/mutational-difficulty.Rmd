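---
title: "Estimating relative mutational difficulty and difficulty-weighted recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative mutational difficulty and difficulty-weighted recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdiff)
```

## The model

The number of cancer samples in which a particular coding mutation is
observed confounds two very different signals: selective enrichment during
tumorigenesis, and the raw ease of generating that nucleotide change.
`mutdiff` separates them by estimating, from a large mutation catalog
itself, a *background rate* for every sequence-context-specific mutation
class, and re-weighting observed recurrence by the inverse of that rate.

A mutation class is the pair (pentanucleotide context, alternate allele):
the mutated base, its two upstream and two downstream neighbours on the
coding strand, and the base it changes into. With 12 substitution routes at
the centre and 4^4 flank combinations this gives 3072 classes. We
deliberately do not collapse reverse complements: transcription-coupled
repair and strand-specific damage make, say, C→T and G→A genuinely
different on the coding strand, and both are reported.

For class $c$ with pentamer $p$:

$$ r_c = \frac{n_c}{s_p \cdot N} $$

where $n_c$ is the class's mutation count after recurrence filtering, $s_p$
the number of times the pentamer occurs in the coding genome (overlapping
windows, counted once per gene using the single major isoform), and $N$ the
number of cancer genomes surveyed. The *relative difficulty* is
$D_c = r_0 / r_c$ with $r_0$ the largest tendency in the pan-cancer table,
so the easiest class has difficulty exactly 1 and everything else is
"$D_c$-fold harder".

Two modelling assumptions are worth making explicit. First, the mutation
catalog minus its highly recurrent events is treated as a draw from the
neutral background: any residual selection on low-recurrence passengers
biases the tendencies. Second, rates are assumed homogeneous across the
coding genome given the pentamer — regional effects (replication timing,
expression level, chromatin state) are averaged over.

### Recurrence filtering

Events present in more than `max_samples` samples (default 5) are removed
before estimation, because strongly selected driver events inflate the
apparent rate of their class. Assessment, by contrast, always uses the full
unfiltered catalog — the whole point is to score those recurrent events.
The threshold is a configuration knob; raising it (10, 20, or no filter)
demonstrably drags the difficulty of known driver classes downward, which
the test suite reproduces on simulated catalogs with a spiked driver.

### Cancer-type-specific tables

Overall mutation burden differs by orders of magnitude between cancer
types, so per-type tables are estimated with the type's own sample count
$N_t$ but scored against the *pan-cancer* $r_0$. A per-type difficulty
below 1 therefore reads "easier in this type than the pan-cancer reference
class", and revised counts summed across types stay on one scale. Types
with fewer than `min_samples` samples (default 100, roughly where the
reference class still expects a double-digit count) are not estimated;
assessment falls back to the pan-cancer table for them, and the fallback is
logged.

## Revised counts and classification

For an event observed $O_t$ times in type $t$,
$R = \sum_t O_t \, D_{c,t}$. $R$ is linear in each $O_t$ and reduces to the
original count when all difficulties are 1.

Labels use strict inequalities: $R <$ `wt_max` (default 700) is
`wt_like`, $R >$ `lof_min` (default 900) is `lof`, the closed interval
in between is `indeterminate`. The bounds are tied to the scale of current
catalogs (they are revised *counts*, not rates) and should be recalibrated
when the catalog grows; both are exposed as parameters.

`calibrate_thresholds()` recalibrates `wt_max` from synonymous mutations,
which are mostly neutral and hence delimit the revised-count range
compatible with retained function. The threshold is the `percentile`
(default 95) order statistic of the synonymous sample, computed as an
inverse-ECDF (type-1) quantile — an actual observed value, robust to single
large outliers and trivially checkable by sorting. Synonymous events above
it are reported rather than discarded: a synonymous change can genuinely
destroy function, e.g. by disrupting a splice site, and deserves a look
rather than silent trimming.

Protein changes that at least one sample acquired through a
multi-nucleotide substitution (e.g. CC→TT producing the same amino-acid
change as a C→T) are flagged. Multi-nucleotide events are too rare to
support their own difficulty estimates, so such events are labelled
`unscored` — unless the SNV-derived revised count already exceeds
`lof_min`, in which case the evidence suffices without the MNV
contribution.

### Zero-count classes

A class with $n_c = 0$ has undefined difficulty (division by zero). The
default policy is to flag it and refuse downstream assessment with an
explicit error; the alternative `pseudocount` policy recomputes the
tendency with $n_c + \alpha$ (default $\alpha = 0.5$, the Jeffreys-style
half count), which keeps full-catalog pipelines running when sparse
per-type tables are in play. The choice is deliberately surfaced rather
than silently defaulted to smoothing, because a smoothed difficulty on a
never-observed class is an extrapolation.

Classes whose pentamer does not occur in the coding genome at all
($s_p = 0$) are structurally undefined and flagged `no_sites`.

## Codon shielding

For a hotspot residue, `shield_report()` asks whether a synonymous recoding
lowers the chance of generating deleterious mutations at that site. The
quantity compared is a sum of *tendencies* (rates), not difficulties —
"chance of generating" lives in rate space. For each of the nine possible
single-nucleotide changes of the codon, the class tendency is added if the
translated amino-acid change is in the user-supplied deleterious set; the
fold reduction is the ratio of this sum before and after recoding. The
deleterious set is an explicit input (for example, all changes labelled
`lof` by the assessment, or a curated list) because no single canonical set
exists per hotspot.

Because contexts reach two bases, recoding a codon also changes the class
assignments of substitutions in the adjacent codons. The report therefore
recomputes, for every residue within `neighbor_window` (default 2) codons,
that residue's summed tendency of *all* amino-acid-changing substitutions
under the original and recoded sequence, and reports the difference. Using
"any nonsynonymous change" as the neighbour target set is a design choice:
neighbours have no user-declared deleterious set, and the total
nonsynonymous rate is the conservative audit of collateral effect. Residues
two or more codons away are provably unaffected (their context windows
cannot reach the recoded bases), which the tests verify numerically.

When a recoding removes every deleterious route the fold reduction is
infinite and flagged `complete_shielding` rather than reported as a number.

## The synthetic-data generator

`synthetic_spec()` / `make_genome()` / `simulate_catalog()` emulate the
statistical structure the estimator assumes: a coding genome of i.i.d.
bases at a set GC content (default 0.52, typical of human coding sequence),
per-class true rates (a baseline of 3e-5 per site, alternate allele and
sample, optionally scaled per substitution route or overridden per class),
cancer types with burden multipliers, and driver events present in each
sample with a fixed enrichment probability. Mutations are per-site
Bernoulli draws, at most one per site and sample, so expected class counts
are exactly $r_c \, s_p \sum_t N_t m_t$ and every recovery test has a
closed-form target. The genome is drawn from the spec's seed and the
catalog from a fixed offset of it, so either can be regenerated
independently.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real catalogs: mutational-signature
mixtures that vary across samples, regional rate heterogeneity along the
genome, indels, sequencing/calling error, and inter-study sample
duplication. It validates the estimator's arithmetic and its sampling
behaviour, not the biological adequacy of the pentamer model.

Validation in the test suite runs at desk scale chosen so that binomial
sampling intervals are informative but fast: 20 genes × 1500 nt (a 30 kb
coding genome), 200 samples, a 10-fold rate contrast between the C→T route
and the rest, five seeds for the recovery test, and a driver at 50%
per-sample prevalence for the filter test. At these sizes the high tier
expects roughly 400–500 mutations per catalog, enough for a 99% interval
of width about ±50% around the true ratio.

## Degenerate inputs and tie-breaks

* Multiple FASTA records per gene: the canonical-transcript list wins when
  supplied; otherwise the longest CDS is kept, ties broken by the
  lexicographically smallest record id, so the choice is deterministic.
* Context windows that overrun a CDS end use the gene's genomic flank
  sequence when provided (sites near exon boundaries); otherwise the site
  is context-unavailable, excluded from class counting, and counted in a
  reported total. Ambiguous (non-ACGT) bases are never imputed.
* Site denominators count windows fully inside each CDS only, while
  numerator contexts at CDS edges may use genomic flanks. The tiny
  asymmetry (at most four windows per gene) is accepted for simplicity and
  documented here.
* Sample identifiers are taken as authoritative for deduplication: one
  sample contributes at most once to an event, however many times it was
  reported.
* Difficulties are kept at full floating precision internally; serialized
  tables carry them at 15 significant digits.

## Limitations

The method scores *generation* probability, not functional impact: it
cannot distinguish a hard-to-generate passenger from a hard-to-generate
driver at equal observed counts, and it inherits every ascertainment bias
of the input catalog (panel composition, exome capture, cohort overlap).
The 700/900 defaults are catalog-snapshot-specific. Per-type tables for
rare cancer types are noisy and deliberately withheld below the sample
floor. Splice effects of synonymous variants are flagged only through
calibration outliers, not annotated.
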