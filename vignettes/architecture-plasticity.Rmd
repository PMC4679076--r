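---
title: "Scoring architecture plasticity potential of domain superfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring architecture plasticity potential of domain superfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archpp)
```

## The model

A protein's *domain architecture* is the N-to-C ordered sequence of SCOP
superfamily domains (and unassigned gap regions) along its sequence. Within
one genome, a superfamily `d` has an *architecture plasticity potential*
`N_d(g)`: the number of distinct architectures of genome `g` that contain
`d` at least once. Counting runs over every protein of the proteome as
given, with no length, score or isoform filtering; identical architectures
carried by several proteins count once, and a domain repeated within one
architecture counts that architecture once.

A functionally coherent *domain set* `ds` — in practice the superfamilies
annotated by one ontology term in a domain-centric annotation resource such
as dcGO — is summarized by the median of its members' counts,

    PP_ds(g) = MED_{d in ds} N_d(g),

the median rather than the mean because per-superfamily counts are heavy
tailed and a single highly plastic member should not dominate the set.
Even-sized sets take the midpoint of the two central values.

Raw medians are not comparable across genomes or across terms of different
sizes, so each observed median is standardized against a randomization
null. `B` times (2000 by default), a set of the same effective size `k` is
drawn uniformly *without replacement* from the genome's **annotatable
universe** — the superfamilies that are present in the genome (`N_d(g) >
0`) *and* annotated by at least one term — and its median recorded as
`PP^b`. With the null sample mean `mu` and standard deviation `sigma`
(`B - 1` denominator),

    PP-score = (PP_ds(g) - mu) / sigma.

A positive score means the set occurs in more distinct architectures than
an equal-size random draw from the same repertoire; a negative score, in
fewer; zero, indistinguishable from chance. Significance is empirical and
directional: for a positive score, `p` is the fraction of null replicates
with `PP^b >= PP_ds(g)` (inclusive); for a negative score, the fraction
with `PP^b <= PP_ds(g)`; a zero score is assigned `p = 1`. P-values are
adjusted across the terms of a genome by the Benjamini–Hochberg step-up
procedure.

Ancestral repertoires come from Dollo parsimony on a rooted, fully
resolved binary species tree: because convergent evolution of the same
architecture in different lineages is rare, each architecture is modelled
as gained exactly once and lost any number of times. The minimum-loss
reconstruction then places the gain at the most recent common ancestor of
the possessing leaves and marks present exactly the nodes of the spanning
subtree connecting them. Counting reconstructed-present architectures per
superfamily at each internal node yields the ancestral count matrix, and
scoring every node on a root-to-leaf path gives a term's lineage
trajectory.

## Parameters that matter

* `B` (default 2000, unit: replicates). The resolution of the empirical
  p-value is `1/B`; 2000 supports FDR thresholds near 0.05 across a few
  hundred terms. Raise it when scanning many terms for small q-values.
* `p_correction` (default `"add-one"`). The literal empirical fraction can
  be exactly 0 at resolution `1/B`, which breaks downstream FDR;
  `(1 + count)/(1 + B)` keeps p in (0, 1]. `"raw"` restores the literal
  fraction.
* `fdr_family` (default `"per-genome"`). Scoring is defined per genome, so
  the BH family defaults to the scored terms of one genome;
  `"global"` pools every (term, node) pair of a trajectory instead, the
  stricter choice when the question is tree-wide.
* `seed`. Every term draws from its own stream derived by hashing
  `(seed, term_id, genome_id)`, so tables are byte-identical across runs
  and invariant to term iteration order. `shared_null = TRUE` reuses one
  null per `(genome, k)` — a legitimate economy when many terms share a
  size, at the cost of correlated null noise between them.

## Design choices where the design was open

* **Sampling without replacement.** A domain set cannot contain the same
  superfamily twice, so the null draws subsets, not multisets.
* **Support of the median.** Term members absent from the genome are
  excluded from the observed median rather than scored as zero: the null
  samples only domains present in the genome, and observed and null
  medians must live on the same support to be comparable.
* **Degenerate nulls.** When the effective set is the whole universe, only
  one subset exists and `sigma = 0`; such terms are reported with status
  `degenerate-null` and no score, never as an infinite score.
* **Universe pooling.** The annotatable universe pools all annotation
  namespaces and levels by default (the `levels` argument restricts it);
  conditioning the null on specificity level is possible but not the
  default, since term-size already captures most of the difference.
* **Gap tokens.** Architectures are compared over domains *and* gaps; runs
  of consecutive gaps collapse to one (an unassigned region's length is
  not informative at this resolution), and `ignore_gaps` drops them
  entirely for analyses where only domain content should matter.
* **Strict inputs.** Duplicate `(genome, protein)` rows and polytomous
  trees are errors, not silently repaired: last-wins overwrites and
  arbitrary polytomy resolution both corrupt counts invisibly.
* **Per-architecture independence.** Dollo reconstruction treats each
  architecture as an independent presence/absence character; no joint
  constraint is imposed across architectures sharing domains.

## What the synthetic generator emulates

`simulate_dataset()` produces the three standard inputs from a known
truth. Per-superfamily diversity targets are drawn from a truncated
discrete power law (`P(N = x) ~ x^-s`): across real proteomes most
superfamilies occur in one or few architectures while a few occur in very
many, and `s ~ 3` reproduces that steep regime (more than 80% of
superfamilies at a single architecture). `build_genome_from_counts()`
realizes targets as tandem repeats of each superfamily (lengths `1..N_d`),
which keeps superfamilies from sharing architectures and therefore makes
the count matrix *exactly* controllable — the round-trip oracle used
throughout the tests. Tree histories are simulated on pure-birth (Yule)
topologies with a single gain per architecture and independent per-branch
losses, matching the Dollo assumptions; branch lengths are ignored
throughout.

What the generator deliberately does **not** model: multi-domain
combinatorics (real architectures share promiscuous domains), terminal
insertion bias in architecture change, isoform redundancy, and any
correlation between a superfamily's annotation and its diversity. Passing
tests therefore demonstrate the statistical machinery — calibration,
sign recovery, reconstruction correctness — not biological realism of any
particular genome.

## Study conditions used by the test suite

* **Null calibration** uses one synthetic genome of 1000 superfamilies at
  the steep regime (`s = 3`) and 200 terms of size 10 drawn uniformly from
  its universe at `B = 2000`: their mean PP-score must lie within ±0.1 of
  zero and no excess of small p-values or `q < 0.05` calls may appear.
  Under this regime the median of a size-10 draw takes only a handful of
  values, so the empirical p-value is *discrete and conservative*; the
  suite therefore checks validity (`P(p <= a) <= a` up to binomial noise)
  rather than exact uniformity, which no correct implementation could
  deliver from a discrete statistic.
* **Planted-sign recovery** runs 100 replicates of a 200-superfamily
  genome at the shallow regime (`s = 1.1`, counts truncated at 200) with
  planted top-10 and bottom-10 diversity terms. The shallow exponent is a
  power consideration fixed in advance: a *low*-plasticity set can only
  reach significance if a random equal-size set's median usually exceeds
  the low counts, i.e. if singleton-architecture superfamilies are a
  minority — at `s = 3` they are ~83% of the universe and the one-sided
  p-value is bounded near 1 for any implementation. At `s = 1.1` both
  planted directions must reach `q < 0.05` with the correct sign in at
  least 95 of 100 replicates.
* **Oracle equivalence** compares the Monte Carlo null (`B = 20000`,
  20 seeds) against exhaustive subset enumeration on universes of 6–12
  domains (`k <= 6`), requiring agreement of moments and tail mass within
  four Monte Carlo standard errors in at least 99% of trials.
* **Dollo correctness** checks `dollo_presence()` against a brute-force
  single-gain oracle on every unlabeled rooted binary shape with up to 6
  leaves under every presence pattern, plus 200 random 8-leaf instances,
  and verifies on 1000 forward-simulated architectures (16 leaves, loss
  probability 0.3) that reconstruction never claims presence the
  generating history did not have.

These problem sizes were chosen so the whole suite exercises every claim
at meaningful precision while remaining quick to run routinely.

## Numerical notes and limitations

* Medians of integer counts are exact in floating point (values and
  midpoints are multiples of 0.5); no tolerance is needed on `pp` itself.
* The Monte Carlo inner loop (partial Fisher–Yates subset draw plus
  selection-based median) is implemented in C++ on R's own RNG stream, so
  results are reproducible from `set.seed()` alone.
* Seed derivation hashes identifiers into `[1, 2^31 - 1]`; distinct terms
  may in principle collide, which would correlate two null streams but not
  bias either.
* The empirical p-value is one-sided in the direction chosen by the data;
  across a fully null family this makes raw p-values behave like the
  smaller of two one-sided tests. Combined with the discreteness of the
  median this is conservative in the regimes tested, but it is a property
  worth remembering when interpreting marginal q-values.
* Dollo parsimony is a lower bound on history: architectures truly gained
  high on the tree but surviving in one clade are reconstructed with a
  later gain, so ancestral counts near the root are conservative.
* Scoring a tree node treats the reconstructed repertoire as if it were an
  observed proteome; uncertainty of the reconstruction is not propagated
  into the null.
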