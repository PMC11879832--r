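---
title: "Sliding-window deductive coding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window deductive coding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(codewindow)
```

## The procedure

`codewindow` automates deductive qualitative coding: given a codebook of
topics with prose definitions, decide for every transcript which passages
carry which codes, and summarize them per code for downstream analysis. The
classifier is an exchangeable component behind a two-method adapter
contract; all pipeline mathematics is deterministic given the verdicts.

The classification primitive is a binary question asked through a six-turn
chat prompt. The system turn fixes the *default-False contract*: the topic
is absent unless the text explicitly proves otherwise. Two demonstration
turns follow (the code's positive example answered `True.`, its negative
example answered `False.`), then the target text. Responses are reduced to
a boolean by their first alphabetic token; anything that is not `true` is a
negative verdict, and tokens that are neither `true` nor `false` are also
tallied as unparseable. This contract makes verbose model output harmless:
trailing rationale can never flip a decision.

Because a full interview exceeds a single prompt, transcripts are scanned
with overlapping windows of consecutive sentences. Two rules define the
windows: a window extends greedily while its word total stays within
`window_max_words`, and the next window starts at the first sentence at
least `min_stride_words` beyond the current start. Detection then works at
the sentence level: each sentence's raw score is the number of positively
classified windows covering it, the score is smoothed with a moving
average, sentences with smoothed score at or above a threshold are
selected, and maximal runs of selected sentences become detected segments.
The initial threshold is a fixed fraction of the *design* maximum overlap
`ceil(window_max_words / min_stride_words)` — derived from the parameters,
not from any transcript, so the threshold is identical across the corpus.
If a code's largest segment exceeds the segment word cap, the threshold is
incremented by one and grouping repeats; the cap exists so every detected
segment fits a single summarization prompt.

## Parameters

All numeric parameters live in one validated object:

```{r}
pipeline_config()
```

| parameter | default | unit | role |
|---|---|---|---|
| `window_max_words` | 300 | words | upper bound on window size; large enough for topical context, small enough for reliable classification |
| `min_stride_words` | 75 | words | minimum distance between window starts; with 300/75 a sentence sits in at most 4 windows |
| `threshold_fraction` | 0.51 | — | fraction of the maximum overlap at which detection starts; `ceil(0.51 × 4) = 3`, i.e. a majority of possible covering windows must agree |
| `segment_word_cap` | 3000 | words | largest admissible detected segment; precondition for one-prompt summarization |
| `smoothing_radius` | 2 | sentences | half-width of the moving average (window of 5) |
| `summary_budget_words` | = cap | words | budget of one summarization prompt |

The smoothing radius is the one parameter with no published value; the
methodology only states that a moving average is applied. The default of 2
sentences is comparable to the sentence scale on which window-overlap
counts change at the 300/75 operating point, and the radius is exposed in
the configuration precisely because it is a package choice, not a given.
Radius 0 disables smoothing and, together with threshold 1 and an
effectively infinite cap, reduces detection exactly to the union of
positive windows — an identity the test suite exploits as an oracle.

## Numerical conventions

* **Words** are maximal whitespace-delimited tokens, punctuation attached;
  one definition is used for windows, segments, budgets and synthetic
  generation alike.
* **Coordinates** are 0-based sentence indices with inclusive spans.
* **Selection is inclusive** (`smoothed >= threshold`): with integer raw
  counts, sentences that exactly reach the threshold are selected, which is
  what makes "counts reaching 3 at threshold 3" meaningful.
* **Edge smoothing shrinks** the averaging window at transcript boundaries
  instead of padding with zeros, so peaks at the start or end of an
  interview are not suppressed.
* **Threshold arithmetic** subtracts an epsilon of 1e-9 before `ceiling()`
  to neutralize binary-representation artifacts (e.g. `0.2 * 5`).
* **Escalation** increments the threshold by exactly 1 per step. Escalating
  to an empty selection drops the code for that transcript with a warning; a
  single sentence longer than the cap is allowed through, flagged, since no
  threshold can split a sentence.
* **Report rounding** is half-up (0.005 → 0.01) at the printed precision of
  the corresponding report: 2 decimals for agreement metrics, 1 decimal for
  frequency factors, whole percents for rating shares. Internal values are
  never rounded.

## The evaluation suite

Level 1 compares verdicts on labeled fragments: per-code TP/TN/FP/FN, from
which the package computes accuracy, *both* rate families, and Cohen's
kappa with `p_e` from the product marginals. A deliberate naming caveat:
published benchmark tables for this workflow print, under "Sens." and
"Spec.", the quantities `tp/(tp+fp)` and `tn/(tn+fn)` — predictive
agreement (PPV/NPV), not the conventional sensitivity/specificity. The
package computes both families under unambiguous names
(`positive_predictive_agreement` vs `true_positive_rate`, etc.) and maps
the report columns to the predictive pair so the benchmark tables reproduce
cell for cell. Kappa bands follow Landis–Koch after half-up rounding to two
decimals.

Aggregation is reported twice and labeled: the **unweighted mean** over
codes (each code one observation — the aggregation behind the benchmark's
mean accuracy and kappa row) and the **pooled** statistics recomputed from
summed counts (the aggregation behind the occurrence table's total row).
They differ whenever per-code item counts are heterogeneous, and neither is
a substitute for the other.

Level 2 reports the relative code-frequency factor (detected segments per
code divided by researcher fragments per code; segment counts, not window
counts, are the package's definition, with window tallies available from
the verdict table) and the dichotomous occurrence accuracy over the
case-by-code grid. Level 3 ingests human ratings (`good`/`adequate`/`poor`)
as data — the pipeline never rates its own summaries — and tallies them per
rater and per code.

For Level-1 dataset construction, negatives are sampled uniformly
(seeded, per code) from fragments not carrying the target code, one
negative per positive by default, mirroring the balanced structure of the
benchmark's per-code item counts; a fragment carrying several codes is
excluded from the negative pool of each code it carries. Few-shot example
fragments are excluded from both sides, and building a prompt whose target
equals an example raises an error rather than silently leaking a
demonstration.

## Summarization batching

"Divide the segments equally over two or more prompts" is ambiguous between
equal segment counts and equal word totals; the package balances **word
totals**, since the budget is a word budget. The split is computed as: find
the minimal number of batches `k` such that an order-preserving split fits
the budget (greedy feasibility check), then minimize the largest batch over
order-preserving splits into `k` parts (binary search on the bound), then
fill greedily under that bound. Order preservation keeps segments in
transcript order inside each prompt. The summarization prompt template —
not published with the methodology — mirrors the classification template's
structure and asks for summaries "citing the original wording where
possible", since references to source text are what make machine summaries
auditable.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical shell of a psychosocial-autopsy
interview corpus: 38 transcripts of 4,000–30,000 words; 33 codes with
heterogeneous prevalence spanning sparse to frequent (a geometric profile
over codes, scaled linearly with transcript length); planted coded
fragments with mean length 207.62 and SD 190.57 words on support ≥ 10. Two
distributional choices deserve explanation:

* **Fragment lengths** are drawn from a shifted gamma whose mean and SD are
  exactly the stated moments. A normal with those values as parameters,
  truncated at 10 words, would have a mean near 260 — truncation at half a
  standard deviation below the mean shifts the first moment substantially —
  so matching the stated moments and the support requires a right-skewed
  law, which is also how empirical fragment lengths behave.
* **Prevalence** defaults to about 40 expected fragments per mean-length
  transcript (≈50% of transcript words inside coded fragments). A corpus
  with fragment counts matching the source study's totals exactly would
  need ~70 fragments per transcript, which cannot be placed without overlap
  in a 4,000-word transcript; the default keeps the heavy-coding character
  while leaving placement feasible at every transcript length.

Transcripts are assembled as alternating filler stretches and fragments, so
fragments never overlap by construction; a configurable share (10%) of
fragments carries a second, overlapping code. Text is language-neutral
token soup with sentence punctuation. Every sentence of a planted fragment
contains its code's marker keyword and filler contains none, which makes
the keyword mock classifier an exact ground-truth oracle: with zero noise
rates its verdict equals "window overlaps a planted fragment of this code".
Noise flips are keyed per (text, code, seed), so verdict streams are
reproducible regardless of evaluation order, and raising a noise rate can
only flip verdicts in one direction — the basis of the monotone-degradation
property test.

What passing tests on this corpus do **not** show: anything about real
discourse. The generator has no semantics, no paraphrase, no topic overlap
beyond shared spans, no Dutch (the source data's language), and no model
hallucination. Recovery results on synthetic corpora certify the pipeline
mathematics — windowing, counting, smoothing, thresholding, batching —
under a classifier of known accuracy, not classifier quality on interviews.

## Problem sizes and runtime choices

The test suite runs window/coverage/grouping oracles on transcripts of
150–200 sentences across several seeds, noise calibration on ≥ 300 probe
windows, fragment-length calibration on ≥ 1,000 planted fragments, and one
end-to-end run at the full default scale (38 transcripts, 33 codes,
~25,000 windows-by-code verdicts), which completes in well under five
minutes on a single CPU with the mock classifier. The recovery property
(100% planted-sentence recall at radius 0, threshold 1) is asserted under
the default study conditions reduced in number of transcripts only —
shrinking transcript lengths or the code set while keeping per-code
prevalence raises coded density into the cap-escalation regime, which is a
different operating point than the property describes.

## Known limitations

* Sentence splitting is deterministic and punctuation-based with a
  protected-abbreviation hook; it does not handle ellipsis-heavy or
  unpunctuated speech transcripts gracefully (everything becomes one
  sentence, which still windows correctly by word count but coarsens
  detection granularity).
* The verdict cache is append-only line-delimited JSON keyed by (case,
  window span, code); changing windowing parameters invalidates it
  implicitly because the spans change, but the file is not versioned.
* Kappa is the two-rater unweighted statistic; weighted kappa and >2 raters
  are out of scope, as is significance testing on kappa.
* A transformer-backed adapter is a documented extension point
  (`classifier_adapter()` with a scalar `classify`), not a shipped,
  tested component: the methodology, not any particular model's weights,
  is what this package implements.
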