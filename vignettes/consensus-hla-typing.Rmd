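---
title: "Consensus HLA typing across an eight-tool panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus HLA typing across an eight-tool panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacombine)
```

## The procedure

`hlacombine` combines the class I HLA genotype calls of a fixed panel of
eight NGS typing tools (arcasHLA, HLA-HD, HLA\*LA, HLAscan, Kourami,
OptiType, PHLAT, seq2HLA) into one decision per sample and locus:

1. **Normalize.** Each raw allele string is parsed into locus, ordered
   numeric field codes, an optional expression suffix and optional
   ambiguity alternatives. Comparison happens at a fixed resolution,
   `n_fields = 2` by default (the four-digit, protein-level type, the
   resolution at which PCR-SBT references are reported).
2. **Filter to available calls.** A call is *available* only when both
   alleles are present, unambiguous, and typed to at least the comparison
   resolution. Multi-allele strings (`03:01/05/06/50`) and two-digit-only
   calls are not guesses we are willing to score — they are unavailable.
3. **Group.** The available calls of a sample are partitioned by genotype
   equality (unordered pair, multiset semantics, suffixes ignored); the
   largest group is the *concordant call* with *agreement size* `n_agree`.
4. **Decide.** If `n_agree >= min_agree` (default 6), the concordant call is
   the genotype; otherwise the sample is escalated with the exact string
   `"Recommend PCR-SBT"`.

The threshold is checked against the panel of eight, not against the number
of available calls: five agreeing tools out of five available is still below
six. This is deliberate — a sample on which three tools abstain carries less
ensemble evidence, and the escalation path (an experimental method) is the
safe default.

### Assumptions

* The consensus rule assumes tool errors are not systematically shared by
  six or more tools at once. The complementarity statistics (below) exist
  precisely to probe that assumption pair by pair.
* All decisions are at two-field resolution; nothing is claimed about
  higher-resolution (intronic/regulatory) differences.
* The reference is treated as ground truth wherever a single unambiguous
  two-field genotype exists for a sample; other samples are excluded from
  accuracy-type metrics (but still count in availability denominators).

## Evaluation statistics

Per tool: availability and accuracy, as percentages (see the README for the
formulas). Per agreement-size group `s`: the tally of concordant calls and
of *true calls* (matching the reference), the pooled accuracy over sizes
`>= s`, and precision/recall/F1 where TP/FP are the true/false calls in the
(pooled) group and FN counts the true calls in all other sizes. Note the
recall denominator is `TP + FN`; defining FN as "the true calls elsewhere"
makes recall the share of all correctly recoverable genotypes that the
group captures, and F1 a trade-off between trusting only large groups
(high precision, low recall) and accepting small ones.

Pairwise complementarity: the correction score of B to A is estimated on the
samples where A has an available, wrong call; it is *undefined* (not zero)
when A is never wrong in the evaluated set, and matrix builders store it as
missing. The complementary score is the symmetric mean of the two
directions; the complementary ratio of B to A is
`(1 - correction(B->A)) * (1 - accuracy(B))` by default. The combining
operator is a configuration switch (`mode = "product"` or `"quotient"`)
because both readings are defensible rescalings; the product is the default
and nothing downstream depends on the choice.

### The combination-accuracy model

*Custom calling* needs an estimate of the probability that the concordant
call of a specific tool combination is correct. The model committed here
anchors on the most accurate tool `a` in the set (ties broken in C-locale
alphabetical order) and chains the other tools' failure-to-correct:

```
P(combination wrong) = (1 - acc(a)) * prod over b != a of (1 - correction(b -> a))
```

returning one minus that, clamped to `[0, 1]`. Properties that motivated
this form: it reduces to `acc(a)` for singletons; it is monotone
non-decreasing as tools are added; it uses only quantities the evaluation
suite already defines (per-tool accuracy, directional correction scores);
and under independent tool errors `correction(b -> a) = acc(b)`, making the
estimate exactly `P(at least one tool in the set is correct)`. Its error is
the usual conditional-independence approximation: corrections are measured
pairwise against the anchor, so higher-order error correlation among the
non-anchor tools is not captured. The test suite quantifies this against a
Monte-Carlo oracle (below). A missing correction score (anchor never wrong
in the training data) falls back to the corrector's accuracy — the neutral
substitute under independence — with a logged message.

Custom calling accepts a concordant call iff the estimate strictly exceeds
the threshold ("over 98%" reads as strict; at the default matrices the
boundary case never arises, so strictness is a tie-break, not a tuning).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_fields` | 2 | comparison resolution (fields); 2 = four-digit protein level |
| `min_agree` | 6 | consensus threshold, counted against the panel of 8 |
| `threshold_pct` | none (user) | custom-calling acceptance threshold, percent, strict |
| `ratio_mode` | `"product"` | operator in the complementary ratio |

The default `min_agree = 6` is where, on the packaged benchmark tallies,
pooled accuracy reaches 97–100% with pooled precision at or above 0.98 for
every locus, while at five concordant calls accuracy drops (91.7–96.1%
depending on locus). Those tallies are shipped as `fixture_spec()` and every
number is recomputed, not hard-coded, by the tests and `scripts/acceptance.R`.

## The synthetic-data module

Two generators, both first-class tested code:

**`simulate_calls()`** emulates a caller panel statistically. Per sample and
locus the reference genotype is drawn from an allele pool (default: ten
synthetic two-field alleles per locus, uniform frequencies); each tool is
then unavailable with probability `1 - availability[tool]` (an unavailable
call is rendered as an ambiguous multi-allele string with probability
`p_ambiguous = 0.5`, else missing), correct with probability
`accuracy[tool]`, and wrong otherwise. Error correlation `rho` acts twice,
mirroring the two ways real tools co-fail: with probability `rho` a tool's
correctness draw reuses a sample-level shared quantile (tools fail together
on hard samples — low coverage, rare alleles — while each marginal accuracy
stays exactly `accuracy[tool]`), and a wrong call copies a previously drawn
wrong genotype with probability `rho` (shared reference-database biases make
wrong calls agree). Wrong genotypes differ from the reference in one allele
by default (`both_allele_errors` flips that), which keeps dissenting calls
distinct under small pools. Defaults for the per-tool availability and
accuracy profiles are shaped like an eight-tool WES benchmark: high
availability for OptiType/HLA-HD/PHLAT/HLA\*LA, low availability for
HLAscan/Kourami, and very low accuracy for the RNA-seq-oriented arcasHLA;
`rho = 0.2` as a realistic mild correlation. These defaults were chosen once
as the simulated study conditions and are documented, not fitted.

What the simulator does **not** emulate: read-depth and read-length effects,
locus-specific error profiles, reference-database version skew, and
tool-specific ambiguity dialects beyond the one multi-allele shape. Tests
passing on simulated panels therefore validate the *statistical machinery*
(estimators recover generating parameters; the combination model tracks a
Monte-Carlo oracle), not any claim about a particular real dataset.

**`realize_fixture()`** is constructive, not stochastic: given a
`group_spec()` (per agreement size, how many concordant calls and how many
of them true), it builds a deterministic call table whose `group_tallies()`
reproduce the spec exactly. In a true block of size `s`, `s` tools call the
reference and the `8 - s` dissenters receive pairwise-distinct wrong
genotypes (so no rival group forms); false blocks share one wrong genotype
among `s` tools. Remaining samples are filler at agreement size 4 — below
any threshold of interest. `fixture_spec()` packages the published
per-group tallies of the two validation cohorts (the 1000 Genomes exome
benchmark: 234/308/309 samples with single-type references for HLA-A/B/C;
and a 39-sample in-house cohort, 38 references for HLA-B). Where a cohort's
tally is printed only as a pooled `>= k` count, the block is placed at size
8: pooled metrics are invariant to the placement, and the suite asserts
exclusive-size values only where exclusive-size counts exist.

## Numerical choices and degenerate inputs

* **Tie-breaks.** Equally large genotype groups are flagged (`tie = TRUE`)
  and broken deterministically by the lexicographically smallest canonical
  genotype key (C-locale byte order, so results are locale-independent). At
  `min_agree = 6` of 8, a tie can never reach the threshold (pigeonhole:
  6 + 6 > 8), so the tie-break never decides a consensus.
* **Undefined metrics error, never silently zero.** Accuracy with no
  available calls, pooled accuracy over an empty pool, precision with an
  empty group and correction scores with a never-wrong conditioning tool
  raise a classed condition (`hla_undefined_metric_error`); matrix builders
  catch it and store `NA`.
* **Rounding.** Metrics return unrounded percentages; reported values are
  rounded half-up to one decimal (`round_half_up()`), not banker's
  rounding, matching how such percentages are conventionally printed.
* **Field codes are zero-padded strings**, never integers: `"1"` parses to
  `"01"`, so `A*01:01` and `A*1:1` are the same allele but field identity is
  string identity, as in WHO nomenclature.
* **Missing rows** (no record for a sample/tool/gene) are indistinguishable
  from explicit `NA` calls in every metric.
* An **empty call table** yields zero decisions and a warning, not an error.

## Problem sizes in the test suite

The suite is sized for a single CPU: brute-force oracle comparisons run 400
random single-sample tables plus per-sample correction recounts on 20-sample
tables; parameter-recovery simulations use 2,000 samples (three binomial
standard errors as the band); the combination-accuracy model is checked
against a Monte-Carlo joint accuracy on a simulated panel of 100,000 samples
with full availability at the default correlation, with an absolute
tolerance of 0.03 chosen to cover the model's conditional-independence bias
at mild correlation; fixture round-trips are property-tested over random
specifications. The packaged cohort fixtures are exact by construction, so
their checks are equalities, not tolerances.

## Known limitations

* The panel is fixed at the eight named tools; other callers can be added
  via `allow_extra_tools`, but the consensus threshold semantics (6 of 8)
  are the validated configuration.
* Class II loci, G/P-group ambiguity resolution and IPD-IMGT/HLA database
  lookups are out of scope; comparison is purely at the two-field string
  level.
* The combination-accuracy model ignores higher-order error correlation; at
  extreme correlation its estimates are optimistic (the vignette's
  Monte-Carlo section quantifies this regime in the tests).
* Native output parsers for the eight tools are not included: the package
  consumes a normalized TSV interchange format, and adapters from each
  tool's files are expected upstream.
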