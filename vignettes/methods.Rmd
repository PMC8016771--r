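---
title: "Methods: priority statistics and text mining for rare-disease patient surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: priority statistics and text mining for rare-disease patient surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endovoices)
```

## The analysis problem

Pan-European surveys of patients with rare endocrine conditions collect
two kinds of data: priority ratings of prespecified research topics on a
3-point scale (1 = very important, 3 = less important), and free-text
answers to open questions. Respondents are stratified by disease area
into eight main thematic groups (MTGs), by gender, age band, country and
advocacy-group membership. The package implements the full analysis of
such a survey as a reproducible pipeline:

1. **Quantitative arm** — per-topic means ± SD, paired t-tests between
   topics, one-way ANOVA across groups with Bonferroni-corrected
   post-hoc pairwise t-tests.
2. **Text arm, whole cohort** — TF-IDF weighting, non-negative matrix
   factorisation (NMF), and selection of the number of topics k by mean
   TC-W2V coherence.
3. **Text arm, per group** — distinctive phrases per MTG by the KLIP
   metric (Kullback–Leibler informativeness and phraseness) against a
   background corpus.

Raw responses from such surveys are typically not deposited, so the
package ships a synthetic-cohort generator with known ground truth;
every downstream stage is tested against quantities that generator
plants.

## Quantitative arm

For topic $t$ the summary is the mean and sample SD (denominator
$n-1$) over non-missing ratings; analyses are complete-case per test
(pairwise deletion), since rating-scale surveys of this kind report no
imputation mechanism. Lower mean = higher priority; topics are ranked
ascending by mean with lexicographic, flagged tie-breaks.

Between-topic comparisons use the paired t statistic
$t = \bar d / (s_d/\sqrt{n})$ with $df = n-1$ on complete pairs. Zero
variance of the differences makes the statistic undefined; the result
is then flagged degenerate with $p = 1$ when $\bar d = 0$ and $p = 0$
otherwise. Between-group comparisons use one-way ANOVA
($F = MS_{between}/MS_{within}$) followed by all $g(g-1)/2$ pairwise
two-sample t-tests with $p_{adj} = \min(1, m\,p)$. Two design choices
were genuinely open:

* **Welch vs pooled post-hoc t.** Group sizes across MTGs are highly
  unequal (tens to hundreds), so Welch's unequal-variance t is the
  default; pooled variance is available (`var = "pooled"`), and the
  $F = t^2$ identity is exercised against the pooled form in the tests.
* **The gender contrast** (classically: fertility, female vs male) is
  run as an independent two-sample test outside the MTG family, so the
  28-comparison Bonferroni factor does not apply to it; respondents
  with undisclosed gender are excluded from that contrast only.

Both raw and adjusted p-values are always reported for the
between-topic paired family (m = 36), since correction practice for
that family varies between studies.

## Corpus preparation

Free text is lower-cased, stripped of punctuation (numerals are kept —
dosage mentions can be numeric), and lemmatised by a deterministic
rule-based lemmatiser: a small irregular-form table plus plural,
participle and past-tense suffix stripping ("sleeping" → "sleep",
"apples" → "apple"). A rule-based lemmatiser was chosen over a
model-based one so that fixtures and rankings are bit-reproducible
without a heavyweight language model; the interface accepts any
drop-in function, and the machine-translation step is likewise a pluggable
function defaulting to a bit-exact identity pass-through (documents on
which a translator fails are retained untranslated and flagged, never
dropped).

Stop words (a fixed shipped English list) are **marked, not removed**:
phrase candidates downstream may contain interior stop words but may
not start or end with one, so original token adjacency must survive
preparation. Deletion decisions belong to the stages that need them —
TF-IDF excludes marked tokens from its vocabulary; phrase extraction
uses the mask only at candidate boundaries.

## Topic modelling and the choice of k

The document-term matrix uses raw term counts weighted by an unsmoothed
idf, $w(d,t) = tf(d,t)\,\ln(N/df(t))$, so a term present in every
document gets weight exactly zero and cannot influence the
factorisation. Raw (rather than log-scaled) term frequency was chosen
because survey answers are short; a double-log weighting would compress
already-small counts.

NMF minimises the Frobenius reconstruction error with multiplicative
updates from a deterministic SVD-based (NNDSVD) initialisation; zero
entries of the initialisation are filled with a small seed-derived
jitter so the updates can move them. Defaults: at most 500 iterations,
relative-improvement tolerance $10^{-5}$; the error trace is recorded
and is non-increasing. Identical input, k and seed give identical
factors.

Topic quality is scored by TC-W2V: the mean pairwise cosine similarity
of a topic's top $t = 10$ words under skip-gram word embeddings trained
on the analysis corpus itself (dimension 100, window 5, 5 negative
samples, 50 epochs, `min_count = 1` so every modelled term has a
vector; single-threaded with a self-contained RNG so a fixed seed gives
bit-identical vectors). Corpus-trained embeddings are the default —
short, domain-specific survey corpora are exactly the case where
general pretrained vectors miss the local usage — but any embedding
matrix with row names can be injected. `select_k` fits one model per
candidate k (default range 2–15) and picks the k with the highest mean
coherence, breaking ties toward the smaller k and flagging them.

## KLIP phrase extraction

Candidates are all 1–4-gram occurrences within a response (never across
responses) that do not start or end with a stop word and occur at least
twice in the group. Three- and four-word combinations repeated by the
same respondent are counted once, so one vocal respondent cannot
dominate a group's ranking. Scoring uses pointwise (per-term) KL
contributions with natural logarithms:

* **informativeness** $= P_{fg}(s)\,\ln\frac{P_{fg}(s)}{P_{bg}(s)}$,
* **phraseness** $= P_{fg}(s)\,\ln\frac{P_{fg}(s)}{\prod_i P_{fg}(w_i)}$
  (exactly 0 for single words),
* **KLIP** $= \gamma\,I + (1-\gamma)\,P$ with $\gamma = 0.8$.

Probabilities are per-phrase-length relative frequencies. The
foreground model is unsmoothed maximum likelihood (candidates always
have positive counts); the background model uses add-1 smoothing over
the union vocabulary of foreground and background n-grams of each
length, because phrases unseen in the background are precisely the
interesting ones and need a finite floor. With $\gamma = 0.8$ the score
is informativeness-dominant; the opposite orientation (γ weighting
phraseness) is supported via `gamma_on`, since the balance-parameter
convention differs between formulations in the term-scoring literature.
Phraseness divides by the *foreground* unigram product — it measures
how much more often the words occur together than apart in the
responses themselves; a background-product variant would conflate
phraseness with informativeness. Ties in the ranking break by
foreground count, then lexicographically.

On corpora of ≤ 100 tokens the entire ranking is checked against a
brute-force oracle that enumerates every n-gram and evaluates both KL
terms literally; agreement is required to $10^{-12}$.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified, and what those
verifications do and do not show.

**Ratings.** Each rating is a Gaussian draw (baseline mean + any
planted (MTG, topic) shift, sd `rating_noise_sd`) rounded to the
nearest integer and clamped into {1, 2, 3} — the simplest mechanism
producing a 3-point scale with controllable group separation. Defaults:
baselines follow published topic means for such cohorts (1.26–1.75),
`rating_noise_sd = 0.6` (published per-topic SDs range roughly
0.36–0.85), missingness completely at random at 2%. Note that
discretisation biases the realised mean away from the latent baseline
(a latent 1.26 yields roughly 1.36 after rounding and clamping);
generator tests therefore check the discretised expectation, not the
latent mean. The nine ratings are drawn independently per respondent;
respondent-level correlation between topics is not modelled and is the
main known gap between the generator and real cohorts — passing
recovery tests show the statistics are computed correctly, not that
real topics are uncorrelated.

**Demographics** follow the published cohort composition (e.g. 78.7%
female, 39.1% Adrenal, 47.1% Northern Europe). One random stream per
sub-generator (cohort, text, background) is derived from the master
seed, so adding one generator never perturbs another's draws.

**Open text.** Each respondent is assigned one latent topic; their
answers are bags of words from that topic's distribution. Defaults:
three disjoint 50-word themes (adrenal-emergency, fatigue-sleep,
fertility-heredity) with $1/\sqrt{rank}$ within-theme decay carrying
0.75 of the mass, a 25-word generic pool shared by all topics carrying
0.25, and 15–35 tokens per answer — content words layered over shared
vocabulary, at the short answer lengths typical of survey free text.
Group-specific ground truth is planted as verbatim multi-word phrases
inserted with probability 0.6 into documents of the matching MTG, with
phrase words deliberately outside the theme vocabularies (they mark a
group the way disease-specific jargon marks real responses). The
background corpus is drawn from an everyday-vocabulary distribution
largely disjoint from the survey themes — a desk-scale stand-in for a
large generic collection such as an encyclopedia dump, which the
package deliberately does not bundle.

What the synthetic corpus does *not* emulate: natural grammar and
function-word structure, multilingual text and translation artefacts,
respondent-specific style, and topic–MTG correlation beyond the planted
phrases. Recovery results on it validate the pipeline's machinery, not
the linguistic realism of any particular survey.

## Verification at the study conditions

The test suite re-derives every expected value from an independent
route: hand-computed TF-IDF tables and ANOVA sums of squares, a
numeric-quadrature Student-t oracle, analytic NMF cases (exact rank-1,
separable block-diagonal), hand-set embedding vectors for coherence,
and the brute-force KLIP oracle. End-to-end experiments run at the
following sizes, chosen to give clear signal at desk scale: k-recovery
on 300 documents (150 respondents × 2 questions) over 10 seeds with
`k_range` 2–6; planted-phrase recovery on 300 respondents against a
50 000-token background; post-hoc power (planted effect 0.4, eight
equal groups of ~200) and family-wise error over 100 simulated cohorts
each; and byte-level determinism of two full pipeline runs under one
seed.

## Numerical conventions and degenerate inputs

* Percentages round half-up to 1 decimal (matching how cohort tables
  are printed); note `round()`'s banker's rounding is *not* used.
* Empty cohorts: `generate_cohort` returns an empty table;
  `demographic_summary` and the test functions raise typed errors.
* Zero-variance inputs are flagged `degenerate`, never silently
  dropped, with the p-value conventions given above.
* All natural logarithms; all probability maps validated to sum to 1
  within $10^{-9}$.
* Region mapping follows the UN Statistics Division M49 split of
  Europe (Eastern/Northern/Southern/Western); unknown countries raise
  an error rather than defaulting to Non-Europe. The shipped table is
  itself under test.

## Known limitations

* The rule-based lemmatiser is intentionally small; it handles the
  plural/participle patterns of survey vocabulary but is not a general
  English lemmatiser.
* Per-MTG topic modelling is deliberately absent (per-group corpora of
  this size are too small for NMF to be meaningful); per-group analysis
  is the KLIP ranking.
* Manual steps that require domain experts — labelling topics, vetting
  extracted terms for clinical relevance — are out of scope; the
  package emits top words and ranked phrases only.
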