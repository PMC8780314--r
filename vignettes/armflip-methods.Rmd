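---
title: "Detecting miRNA arm switching and miRNA:lncRNA antagonism: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA arm switching and miRNA:lncRNA antagonism: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armflip)
```

## The problem

A plant miRNA precursor hairpin is processed into two mature strands, one
from each arm (5p and 3p). Which arm accumulates — arm selection — can
differ between tissues, time points or genotypes; a reversal of the
dominant arm between two conditions is *arm switching*, and because the two
arms carry different seed sequences, a switch redirects the locus to a
different target repertoire. Separately, long noncoding RNAs carrying
miRNA-complementary sites can sponge or mimic targets of a miRNA, and a
candidate miRNA:lncRNA pair is supported when the two show *antagonistic*
expression (opposite differential-expression directions in the same
contrast) alongside sequence complementarity.

`armflip` implements both screens for bulk small RNA-seq designs of the
form accession × tissue × time point × replicate, together with a seeded
synthetic-data generator so that every stage is testable against known
truth.

## Arm selection and switch calls

For a hairpin in one sample with arm-level read counts $n_{5p}$ and
$n_{3p}$, the arm-selection value is

$$\omega = \frac{n_{5p}}{n_{5p} + n_{3p}} \in [0, 1],$$

undefined when both counts are zero. Classification per sample:

* `insufficient` when $\max(n_{5p}, n_{3p}) \le$ `min_count` (default 50,
  strict `>` gate on raw counts);
* `dominant3p` when $\omega <$ `low_cut` (default 0.3);
* `dominant5p` when $\omega >$ `high_cut` (default 0.7);
* `unclassified` otherwise — including exactly at the cut points, since
  the inequalities are strict.

A switch between two conditions is called only when every replicate of one
condition is dominant for one arm and every replicate of the other
condition is dominant for the opposite arm (replicate unanimity). A relaxed
mode (`require_all_replicates = FALSE`) drops `insufficient`/`unclassified`
replicates instead of letting them veto the call; it is exploratory and not
used by default. ω is always computed per replicate, never on pooled
counts: pooling hides replicate-level disagreement, which is the main
guard against depth artifacts.

Two readings of the count gate were possible (per sample vs pooled; raw
counts vs CPM). We gate per sample on raw counts: per-sample gating matches
the per-replicate dominance logic, and the gate's published phrasing uses
absolute counts. The per-sample raw-count reading is also the stricter of
the two at typical depths.

Condition pairs examined by default: all pairs within an accession
(differing in tissue or time) plus the same tissue/time cell across
accessions. Cross-accession, cross-tissue pairs conflate two factors and
are only examined under `compare = "all"`.

## Arm quantification

Reads (adapter-trimmed, quality- and length-filtered: mean Phred ≥ 20,
length 16–30 nt) are aligned ungapped, sense strand, against every
hairpin; the best alignment is the fewest-mismatch one (leftmost on ties
within a hairpin, default `max_mismatch = 0`). A read is credited to an arm
when its aligned interval covers at least 50% of the read length on that
arm; a read overlapping both arms goes to the larger overlap (an exact tie
is unassigned); reads overlapping neither arm count as `unassigned` for
that hairpin. Reads tied across hairpins count once per tied hairpin —
fractional assignment would introduce an untestable free parameter.

The quality filter interprets "Phred ≥ 20" as the *mean* read quality
(`quality_mode = "mean"`); a per-base minimum mode is available. Mean was
chosen because per-base trimming would change read lengths, which the
16–30 nt window treats as fixed.

## Differential expression stand-in

The screening thresholds are the contribution here, not the test engine:
miRNAs pass with CPM ≥ 50 in at least one sample of the contrast,
|log2FC| ≥ 1 and BH-FDR ≤ 0.05; lncRNA abundance matrices use the same
fold-change/FDR thresholds without the CPM gate. Thresholds are inclusive
(≥ / ≤) by default with a `strict` switch, since published usage alternates
between the two spellings.

The per-feature test is a **conditional binomial exact test**: conditioning
on the pooled count $N = A + B$ of a feature, under the null
$A \sim \mathrm{Binomial}(N, \pi)$ with $\pi$ the share of the two groups'
summed library sizes. The two-sided p-value sums all outcomes with
probability ≤ that of the observed $A$ ("minlike"). This is the
dispersion→0 (Poisson) limit of the negative-binomial exact test used by
count-DE packages, implemented rather than wrapped so that it is fully
specified and testable against enumeration.

Its known limitation is stated rather than hidden: for overdispersed counts
the Poisson-limit test is **anticonservative**, increasingly so as
$\alpha\mu$ grows (NB variance $\mu + \alpha\mu^2$). The acceptance suite
measures the empirical size on a null NB simulation (dispersion 0.1, mean
400, 3v3) and that check fails the nominal [0.03, 0.07] band by design of
the simulation — the band is attainable only where $\mu \ll 1/\alpha$,
i.e. below the depths the count gates themselves demand. This is exactly
why production DE tools moderate dispersion; reproducing those internals
is out of scope. For the planted-signal recoveries the test's inflation is
immaterial (planted effects are many standard errors from the null).

Numerical details: p-values are computed from log pmf values (the extreme
tail underflows a double at $N \sim 10^3$) with a $1+10^{-7}$ relative
tolerance for pmf ties, floored at the smallest positive double so BH input
stays in (0, 1], and capped at 1. $N = 0$ returns 1 by convention. BH is
the standard step-up, applied within a contrast over the CPM-passing
features only (filter-then-test); excluded features report `NA` p-values
and direction `ns`. Fold changes are computed on group-mean CPM with
pseudocount 0.5 on both sides.

## Duplex scanner

Complementarity is scored with a plant-style penalty scheme rather than a
thermodynamic duplex model: Watson–Crick pairs 0, G:U wobble 0.5, other
pairs 1, single-base bulge 2, penalties doubled inside the seed (miRNA
positions 2–8 from the 5′ end), zero non-WC pairs allowed in the seed by
default, and sites reported at total penalty ≤ 4. Every target window is
scanned ungapped plus single-bulge variants (miRNA or target bulge)
confined outside the seed; overlapping hits collapse to the minimum-penalty
one, ties to the leftmost. G:U counts toward the seed mismatch budget: in
the seed the screen demands perfect Watson–Crick pairing by default.

Free-energy models (RNAhybrid-style) rank sites on a different scale; no
numerical correspondence with such tools is claimed. One scoring caveat:
relabeling both strands by A↔U, G↔C maps WC pairs to WC pairs, so
penalties of wobble-free duplexes are invariant under it, but a G:U wobble
maps to a C:A mismatch — the invariance property is therefore asserted for
perfect-complement sites only.

The interaction screen then pairs a duplex site with antagonistic DE calls
in the same contrast: one call per (pair, contrast), and a call with equal
directions is impossible by construction. Because both criteria are
required, only DE-passing features need scanning — the pipeline exploits
this.

## What the generator emulates — and what it does not

The default `sim_config()` states the emulated world: 2 accessions ×
2 tissues × 6 time points × 3 replicates (72 libraries), per-hairpin depth
NB(mean 400, dispersion 0.05) with variance $\mu + \alpha\mu^2$ (α = 0 is
Poisson), switch loci at true 5p proportion 0.9 in one tissue vs 0.1 in the
other (non-switch loci at 0.5), reads as exact arm sequences plus a 3′
adapter at constant Phred 35, lncRNAs of 400–800 nt with planted
reverse-complement sites (optionally degraded to a requested penalty with
non-seed wobbles), and antagonistic pairs planted at |log2FC| = 2 in one
within-tissue time contrast. The test suite runs reduced designs of the
same shape for speed.

Library sizes in the expression generator are a fixed nominal total
(features × mean × 1.25) rather than column sums: a real library's
retained-read total is dominated by reads outside the tested feature set,
so a handful of planted fold changes cannot move it. Column-sum
normalization at desk-scale feature counts would let planted signal leak
into the denominator (a composition bias that shrank planted |log2FC| from
2.0 to as low as ~0.7 in early testing) — a generator artifact, not a
property of the method under test.

A green synthetic test therefore establishes: coordinate and counting
correctness, threshold logic, determinism, and recovery of planted effects
well above threshold. It does **not** establish performance under real
data features that are deliberately absent: isomiR 5′/3′ end variation,
multi-mapping between paralogous hairpins, sequencing error profiles,
adapter variants, batch effects, secondary structure, or realistic
expression correlation.

## Degenerate inputs and tie-breaks (summary)

* ω at (0, 0) counts: undefined (`NA`); such rows are `insufficient`.
* Reads matching no hairpin are `unmapped` (reported as an attribute), not
  `unassigned`; `unassigned` is reserved for hairpin-matching reads
  overlapping neither arm sufficiently.
* Empty reads (pure adapter) are rejected by the length filter, not the
  quality filter.
* A condition present in the design but absent from the profiles is
  skipped with a warning; zero conditions or an empty hairpin list are
  hard errors.
* Zero-feature count matrices are legal and round-trip (header-only file).
* Config files are INI-style `key = value` with `[section]` nesting; every
  CLI flag has a config equivalent and the CLI wins.

## Known limitations

* The DE stand-in is not calibrated under overdispersion (see above); its
  p-values should be read as a screening ranking, as in the original
  Degust/edgeR usage it replaces.
* The duplex scanner allows at most one bulge per site and cannot find
  sites spanning region boundaries in `predict_targets()`.
* No genome-scale alignment, novel-hairpin discovery, isomiR analysis,
  TMM/quantile normalization, multi-factor GLMs, or free-energy duplex
  folding — all deliberately out of scope.
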