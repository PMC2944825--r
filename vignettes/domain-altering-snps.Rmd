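---
title: "Domain-altering SNPs and edgetic network perturbation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-altering SNPs and edgetic network perturbation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainsnp)
```

This vignette documents the models, numerical choices and design decisions
behind `domainsnp`, and what the synthetic benchmark does and does not
establish about real data.

## Domain signatures

**Patterns.** A pattern is a restricted regular expression over the 20
standard amino acids: elements joined by `-`, where a letter matches
exactly, `[...]` a set, `{...}` a complement set, `x` anything; any element
may repeat `(n)` or `(n,m)`; `<` and `>` anchor to the termini. Scanning
reports, at every start position, the single span obtained by resolving
variable repetitions greedily (longest first, element by element) —
classic greedy regular-expression semantics, which the implementation
realises by compiling patterns to PCRE and collecting overlapping matches
through a capturing lookahead. The choice of longest-per-start makes match
*counts* well defined, but classification only ever consumes the
presence/absence of an overlapping match, which is unaffected by that
choice. Zero-length expansions (possible when every repetition admits zero
occurrences) are not matches: a domain occurrence must cover at least one
residue.

**Profiles.** A generalized profile is an L x 20 position score matrix with
affine gap penalties (`gap_open` for the first, `gap_extend` for each
further skipped residue or profile position) and a presence cutoff. The
matching score MS is the best *local-local* alignment score: unaligned
flanks are free on both the sequence and the profile side, internal gaps
are penalised, at least one profile position must be matched, and no zero
floor is applied (MS can be negative). Local-on-both-sides was a genuine
design choice — the alternative (profile consumed globally, end deletions
penalised) is equally implementable, but local ends are what "best local
alignment" means in the Smith-Waterman tradition and they make MS
insensitive to where a domain sits inside a longer protein. Gap runs of
the two kinds are penalised independently, so a deletion run may directly
follow an insertion run, each opening its own affine gap. Ties between
equal-scoring alignments resolve to the smallest start, then the smallest
end. The DP is implemented in C++ (one row of three affine states, with
start-coordinate propagation for span reporting) and is validated against
exhaustive enumeration of all alignments for short instances.

Since the downstream statistic is a *ratio* of matching scores, no attempt
is made to calibrate absolute score scales across profiles; cross-domain
comparability of DD under different score scalings is a known limitation.

## SNP classification

Applying a missense SNP substitutes one residue. For every reference match
whose span contains the SNP position the classifier emits one call
(multiple spans of the same pattern domain collapse to one call per
domain — the verdict depends only on the domain, so duplicate rows would
double-count):

* **Pattern domains**: the mutated sequence is rescanned; if no surviving
  match of that pattern overlaps the SNP position, the call is
  domain-altering by *pattern loss*. Any surviving overlapping match —
  possibly shifted — means not altered: only the presence bit matters.
* **Profile domains**: the mutated sequence is rescored, and the domain
  distortion DD = (MS_ref − MS_alt)/MS_ref is compared to the DD cutoff
  (default 0.10, within the empirically observed 0–0.3 range of such
  scans). The comparison is inclusive (DD ≥ cutoff); DD is clamped below
  at zero, so score-improving substitutions never "distort". If MS_alt
  falls below the presence cutoff while MS_ref was above it, the domain is
  erased outright and the call is domain-altering regardless of DD — the
  profile analogue of pattern loss.

A SNP inside two overlapping domains yields two independent calls; a SNP
inside no match is `outside`. Calls carry DD, both matching scores and the
erasure flag, so the per-SNP rollup can be re-evaluated at any cutoff
without rescanning — this is what the DD sweep does.

## Enrichment

All enrichment uses the exact hypergeometric upper tail P(X ≥ k),
evaluated through the log-scale cumulative distribution so extreme
enrichments do not underflow. The DD sweep takes all D-SNPs as the
population and the DA-SNPs at each cutoff as the sample; pattern-loss and
erasure SNPs belong to the sample at every cutoff. One-tailed testing is
used throughout because only over-representation is of interest. The sweep
is reported unadjusted (one row per pre-registered cutoff); generic term
enrichment (`term_enrichment()`, for user-supplied GO/pathway-style
mappings) applies Benjamini-Hochberg q-values across terms and reports at
a configurable raw-p cutoff (default 0.01). Disease annotations can be
matched at SNP or protein level (default SNP).

## Network impact

The score matrix counts, over every PPI edge and both orientations, how
often an alterable domain on one endpoint co-occurs with a signature
(domain or linear motif) on the partner. Each pair (d, s) is tested
against a random-partner background. The paper-style background —
re-drawing binding partners at random — is under-specified (number of
draws, degree preservation), so the default is its closed-form
expectation: a hypergeometric over the proteome with sample = the distinct
partners of d-carrying proteins (distinct partners, not edge multiset,
because curated PPI edges are unique pairs). An explicit empirical mode
(uniform partner resampling, seeded, 1000 draws by default, estimator
p = (1 + #{null ≥ observed})/(1 + draws)) is provided for fidelity to the
resampling formulation; the two agree in rank order on synthetic networks.

Enriched pairs are tiered by reference evidence: `ddi_reference` (known
domain-domain pair, order-normalized), `domain_motif_reference` (known
(domain, motif) pair, ordered), else `enrichment_only`. An edge incident
to a protein with a DA-SNP in domain d is called broken when the partner
carries at least one enriched signature s for d at an admitted tier; the
altered domain itself must be the row signature — the host protein's other
domains do not contribute. Tightening `min_tier` can only un-break edges.
Connectivity reports count each edge once per DA-protein even when two
altered domains break it, so `n_broken + n_intact` always equals the
evaluated degree.

## The synthetic universe

`generate_universe()` builds, from one seed, a complete input set with
ground truth. Defaults (300 proteins of 80–400 residues, 6 pattern + 6
profile domains, 6 motifs, Poisson(2) SNPs per protein, in-domain fraction
0.2, DA fraction 0.05 of in-domain SNPs, disease base rate 0.06, DA
disease odds ratio 2, 5 binding rules, 2 edges per protein, rule fidelity
0.9) mirror the gross proportions of a proteome-wide missense scan: about
one SNP in five in a domain, about one in-domain SNP in twenty
domain-altering, about 6% of in-domain SNPs disease-annotated.

Constructive guarantees, rather than rejection sampling, make the ground
truth exact:

* Profile domains score 2 at consensus positions, 4 at one internal
  high-weight position, −2 otherwise; the presence cutoff is 60% of the
  consensus score. A damaging SNP replaces the high-weight internal
  residue, dropping MS by 6 and guaranteeing DD ≥ 6/(2L+2) ≥ 0.15 for
  L ≤ 15 — analytically above the 0.10 cutoff. One designated benign
  position scores its alternative residue equally, so the benign
  substitution has DD = 0 exactly.
* Pattern damaging SNPs substitute a residue that violates an element's
  class; benign SNPs use wildcard or within-class alternatives. Every
  planted SNP is verified against the actual scanner/classifier and
  redrawn on mismatch (up to 100 attempts); a damaging SNP that cannot be
  verified is never emitted.
* Planted signatures are **mutually exclusive**: a protein carries at most
  one planted domain or motif (70% / 25% of proteins), and generated
  patterns/motifs are required to have an expected chance-match count
  below ~0.3 over the whole proteome (element compositions are redrawn
  until the per-window match probability is small enough). Both choices
  exist to keep the planted truth identifiable: if carrier sets overlap —
  through co-planting or through promiscuous patterns — an edge generated
  by one rule genuinely realises other signature co-occurrences, and
  "false positives" of the recovery benchmark would be real, unlabelled
  signal rather than noise.
* Edges are sampled from the rule-eligible carrier pairs (fidelity
  fraction) plus uniform noise; at fidelity 1 an exhausted rule pool
  shrinks the network rather than diluting it.

Disease labels are Bernoulli per SNP with log-odds shifted by
log(odds ratio) for intended DA-SNPs. Protein-level annotations are
derived for proteins hosting a diseased SNP so both matching levels are
exercised.

**What the benchmark does not show.** Real proteomes have biased residue
composition, homologous domain families, isoforms, scale-free interaction
topology and correlated annotations; none of these are emulated. Passing
the synthetic benchmark demonstrates that the machinery is correct and
calibrated under its stated model, not that effect sizes on real data will
match.

## Statistical power at the default scale

With the default proportions a universe contains roughly 120 D-SNPs and 6
DA-SNPs. The null calibration of the sweep p-value is sound (the fraction
of null universes with p < 0.05 sits at ~0.015, conservative because the
test is discrete at these counts). Detection of a disease odds ratio of 2
among ~6 DA-SNPs is, however, information-limited: reaching p < 0.05
requires at least 2 annotated DA-SNPs, an event with probability ~0.14
under the alternative — an analytic ceiling no test can exceed at this
sample size. The package reports this honestly; studies needing power for
odds-ratio-2 effects must simulate larger universes (more proteins, more
SNPs, or a higher DA fraction).

## Numerical choices and degenerate inputs

* Scanning problem sizes used in the shipped tests: proteomes of 80–300
  proteins, 12 domain signatures, oracle checks on 1000 random pattern
  instances and 500 random profile instances, hypergeometric exactness on
  all contingencies with N ≤ 60; these sizes keep the full suite and the
  reproduction script to a few minutes on one CPU.
* Profile oracle tests draw scores on a 0.25 grid so alignment-score sums
  are exact in binary and tie-breaking is tested on genuine ties.
* `hypergeom_upper(k = 0)` returns 1 exactly; invalid contingencies error.
* DD with MS_ref ≤ 0 is undefined and errors (cannot occur for called
  domains, whose presence cutoff is positive).
* Empty inputs (no SNPs, no domains, no edges, no enriched pairs)
  propagate as empty tibbles with stable schemas, never as errors.
* All randomness flows through explicit seeds (`withr::with_seed`);
  pipeline outputs contain no timestamps, so identical configurations
  produce byte-identical output trees.

## Known limitations

* Only single-residue missense substitutions are modelled; stop-gains,
  frameshifts and multi-residue variants are out of scope.
* One sequence per protein id: isoform mapping is the caller's problem.
* PROSITE's full `.dat` grammar, circular profiles and score-level
  normalisation are not implemented; the domain-definition dialect covers
  patterns and plain score-matrix profiles only.
* The random-partner null ignores degree structure; the empirical mode
  resamples partners uniformly, not degree-preservingly.
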