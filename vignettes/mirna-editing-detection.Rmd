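---
title: "Detecting miRNA editing events: model, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA editing events: model, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredscan)
```

`miredscan` calls candidate RNA editing sites in mature microRNAs from
small RNA sequencing reads, classifies them, and characterises their
sequence context and target-redirection potential. This vignette is the
package's account of the underlying model: what is assumed, which knobs
exist, why the defaults are what they are, and what the validation
experiments do and do not demonstrate.

## The detection model

### Alignment

Reads are mapped directly to pre-miRNA hairpin references, sense strand
only, with at most one mismatch and no indels. A read is retained only if
exactly one (hairpin, offset) location attains the best mismatch stratum:
a single 0-mismatch hit wins outright and suppresses all 1-mismatch hits;
two or more equally good locations make the read *ambiguous* and it is
discarded (and tallied). The one-mismatch ceiling is what makes single-base
editing detectable while keeping the mapping unambiguous for ~22-base
reads; it also means a read carrying an edit *plus* a sequencing error is
lost, which slightly depresses observed editing levels (see *Limitations*).

Internally the aligner indexes every hairpin substring at the lengths of
the two read halves. Any placement with at most one mismatch must match one
half exactly (pigeonhole), so looking up the two halves enumerates every
admissible candidate, which is then verified base by base. The test suite
checks this machinery against a brute-force enumeration of all (hairpin,
offset) pairs on hundreds of random instances; the two must agree exactly.

Mismatches at read ends count like internal ones (no soft-clipping), and
reads mapping equally well to paralogous hairpins with identical mature
sequences are discarded as ambiguous rather than assigned arbitrarily —
a conservative choice that loses signal in duplicated families but never
mis-assigns it.

### The binomial sequencing-error model

At each covered hairpin position the pileup records the coverage $n$, the
count $k_b$ of each alternate base $b$, and the mean Phred-implied per-base
error probability $\bar e$ over all read bases at the site. Under the null
hypothesis that an alternate base arises only from sequencing error, and
with errors spread uniformly over the three possible wrong bases, the count
for one specific substitution is

$$ K \sim \mathrm{Binomial}\!\left(n, \; \bar e / 3\right), $$

and the site's evidence for editing is the upper tail $P(K \ge k_b)$,
computed exactly. The division by 3 matters: without it the null error rate
per specific substitution is overstated threefold and power is lost. Using
the *site-mean* error probability (rather than the qualities of the
mismatching reads only) is the package's choice where conventions differ;
with the simulator's constant quality strings the two coincide.

Per sample, every (site, alternate) pair with $k \ge 1$ enters a Bonferroni
family of size $m$; $p_{\mathrm{adj}} = \min(1, m\,p)$. A call is
significant iff

* $p_{\mathrm{adj}} < \alpha$ (default $\alpha = 0.05$),
* coverage $n \ge$ `min_cov` (default 10 reads), and
* editing level $k/n \ge$ `min_level` (default 0.01).

Correction is applied per sample, mirroring per-library processing; an
alternative would be one family across all samples, which is stricter for
large cohorts. All three thresholds are explicit configuration keys and are
recorded in the run log.

### DNA-level and artefact filtering

A site that differs from the reference in the DNA itself is a polymorphism,
not editing. Calls whose (hairpin, position) carries a known DNA variant
are removed; matching is positional by default (catalogue overlap
semantics), with an allele-exact mode and a flag-only mode (genome-encoded
variants do remain in the transcript, so some analyses prefer flagging to
removal). Variants supplied in a parent coordinate system are lifted onto
hairpins with strand-aware allele complementing. Separately, the entire
A-to-C substitution class is excluded: on Illumina chemistry that class is
dominated by a sequencer-specific artefact, and a class-wide exclusion is
the only safe treatment. Both filters only ever remove calls, are
idempotent, and commute.

### Classification, recurrence, summaries

Calls are projected onto mature coordinates (1-based from the mature
5′ end). The seed is mature positions 2–8 inclusive — note position 1 is
*not* seed. A-to-G calls are reported as A-to-I (inosine pairs as
guanosine at the sequencer) and C-to-T as C-to-U; these two classes are
canonical, everything else non-canonical. Labels use the RNA convention
(G-to-U, not G-to-T) while all sequence handling stays in the DNA alphabet
— a single internal alphabet avoids an entire class of U/T bugs.

An event's identity is (mature miRNA, arm, mature position, substitution
type). Identical events are merged across samples; recurrence is counted
per tissue, and an event is *recurring* when at least `recur_threshold`
(default 3) samples of one tissue carry it. Summary percentages (seed
share, per-type shares) are computed within category and tissue, rounded
half-up to two decimals, and reported as `NA` — not 0 — when the
denominator is empty.

### Sequence context and triplet statistics

For each edited site the hairpin bases at positions −1 and +1 are
collected (always from the hairpin, so mature-terminal sites still have
context; sites at the first or last hairpin base are excluded and
counted). Each flanking base's frequency is tested against a null
proportion with a two-tailed z test,
$z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/n}$; the exact binomial test is
available as an option, and for moderate event counts the two can differ
noticeably away from small p-values — the z test is the default because a
plain test of proportion is the convention for this analysis. The null
$p_0$ defaults to uniform 0.25; the base composition of the reference set's
mature sequences (`mature_base_freqs()`) is the exposed compositional
alternative, and which null is used is recorded with the profile.

Triplet statistics count every overlapping 3-mer across the hairpins
(`triplet_spectrum()`, 64 frequencies summing to 1) and compare
edited-site context triplets against them as enrichment ratios; a zero
background with nonzero edited count is reported as infinite and flagged
rather than silently dropped.

### Target overlap

The target predictor is deliberately minimal: a UTR is a target iff it
contains the reverse complement of mature bases 2–8 (exact 7mer-m8 match;
an 8mer variant adds the 3′ A anchor). It exists so that seed-editing
target redirection is demonstrable end to end on synthetic UTRs; it is in
no way a substitute for thermodynamic, conservation-aware or consensus
prediction, and its outputs should not be compared with such tools. The
overlap statistic itself — 100 · |before ∩ after| / |before|, half-up to
two decimals — also accepts bare counts, so published target tallies can
be re-checked directly.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
package's reference study conditions: a paired two-tissue design with nine
samples per tissue; 50 hairpins of 70–110 bases carrying 5p and/or 3p
mature arms of 20–23 bases; 100,000 reads per sample; log-normal
per-mature relative abundance (σ = 1); constant Q30 base quality
(error rate 0.001); 50-base instrument reads with a TruSeq-style 3′
adapter read through when the insert is shorter. Editing is injected per
site: with probability `editing_level` a read covering the site receives
the alternate base, *then* independent per-base errors substitute a
uniformly random different base — so the expected observed alternate
fraction is $\ell(1-e) + (1-\ell)e/3$, which the property tests verify.
Everything is deterministic given the seed, byte-for-byte.

Choices the data do not dictate were fixed once: the expression model is
log-normal because miRNA abundance spans orders of magnitude; error
substitutions are uniform over the three alternatives as the simplest null
consistent with one error-rate parameter; qualities are constant Q30 with
an optional jitter because instrument profiles vary and the detection
model consumes only the encoded probabilities. The generator does *not*
emulate ligation bias, position-dependent quality decay, cross-mapping
from elsewhere in a genome, isomiR length heterogeneity (reads are full
mature arms by default) or PCR duplication. Consequently, passing
validation here shows the *caller's statistics* behave as designed under
its own error model — not that real libraries satisfy that model.

## Validation experiments

Two experiments quantify the caller, both exported:

* `fwer_null_experiment()` — error-only samples (no injected edits) at the
  reference scale (50 hairpins, 100k reads, Q30); the fraction of
  replicates with at least one significant call estimates the family-wise
  false-call rate, which per-sample Bonferroni correction controls at
  α. Across 200 replicates the acceptance suite requires it below
  $0.05 + 3\sqrt{0.05/200} \approx 0.097$; observed rates are near zero
  because the level and coverage gates discard the marginal rejections the
  discrete Bonferroni bound would otherwise admit.
* `edit_recovery_experiment()` — plants a seed edit, a non-seed edit, an
  A-to-C edit and a DNA-variant-masked edit, and scores exact-identity
  recovery (miRNA, mature position, substitution label, seed flag) over
  replicates, conditioning on realized site coverage ≥ 100. Detectable
  edits at levels ≥ 0.1 must be recovered in ≥ 95% of replicates; the
  excluded classes must never surface. These are properties of the chosen
  default thresholds, verified empirically.

Problem sizes in the test suite (hairpin counts, read depths, replicate
counts) are the package's reference conditions stated above; the
acceptance script runs a scaled two-tissue study (20 hairpins, 20k reads ×
18 samples) plus both experiments in well under a minute.

## Numerical and degenerate-input conventions

* Binomial tails via `pbinom`'s exact machinery; $k=0$ gives 1 by
  construction.
* Percentages round half away from zero (so 44.2478% prints 44.25, where
  truncating conventions print 44.24); tests on published-style summaries
  therefore carry a ±0.01 tolerance.
* Empty inputs are legal throughout: zero hairpins, zero reads, an empty
  variant table, a sample with no events, and an all-filtered call set all
  produce empty, well-formed tables rather than errors.
* `proportion_test` refuses $p_0 \in \{0, 1\}$; `overlap_stat` refuses an
  empty before-set (the percentage is undefined, not 0).
* Ties in the aligner are never broken: equal-best locations mean the read
  is discarded as ambiguous.
* All derived seeds stay below $2^{31}$; a run's outputs are reproducible
  byte-for-byte from (configuration, seed) alone, excepting the log
  timestamp.

## Known limitations

* A 1-mismatch alignment model cannot see a read carrying both an edit and
  a sequencing error (expected loss ≈ 2% of edited reads at Q30 and 22-base
  reads), cannot call indel editing, and cannot detect two edits on one
  read.
* Per-sample Bonferroni correction is conservative; borrowing strength
  across replicates (an empirical-Bayes treatment) would raise power at
  low editing levels but is out of scope.
* The A-to-C exclusion removes genuine A-to-C editing along with the
  artefact — an accepted cost, as the two cannot be separated without
  orthogonal chemistry.
* Editing levels are biased slightly downward by the edited-read alignment
  loss above; at Q30 this is well inside the binomial noise at realistic
  coverage.
* The seed-match target predictor ignores thermodynamics, conservation and
  3′ compensatory pairing; its overlap percentages demonstrate redirection
  qualitatively only.
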