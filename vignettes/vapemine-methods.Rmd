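---
title: "Methods: aspect importance and opinion summarization for e-liquid reviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aspect importance and opinion summarization for e-liquid reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapemine)
```

## The problem

Review sites for e-liquids (the flavored liquids aerosolized by electronic
nicotine delivery systems) collect, alongside free text, an overall 1–5
rating and four 1–5 aspect ratings: flavor accuracy, throat hit, value, and
cloud (vapor) production. Two questions drive the analysis this package
implements. First, *which aspects most influence a user's overall
sentiment* toward a product? Second, *why* — which concrete opinions
("harsh throat hit", "steep price") accompany positive and negative
experiences? The first is answered with a decision-tree importance
statistic over discretized ratings; the second with dependency-pattern
opinion extraction over the review text, aggregated into per-flavor and
per-product summaries. Such summaries are of interest for tobacco-product
surveillance: concentrations of negative opinions on specific aspects can
act as early signals about product classes.

## Discretization

All ratings are mapped onto a three-valued sentiment scale by a fixed
partition of $[1, 5]$:

$$
\mathrm{label}(r) =
\begin{cases}
\text{positive} & r \ge 4 \\
\text{neutral} & 3 \le r < 4 \\
\text{negative} & r < 3.
\end{cases}
$$

Ratings are handled as reals, not integers, because the same rule is
applied at product level to the *mean* of a product's overall ratings (a
product with ratings 5, 4, 3 has mean 4.0 and is a positive product — the
boundary belongs to the upper class). Missing aspect ratings are explicit
`NA`, never 0: a zero sentinel would silently discretize as negative.

## Aspect importance via ID3

For importance analysis, only reviews with all four aspect ratings are
used (`filter_complete()`), since the tree conditions on all four labels.
An ID3 decision tree is grown predicting the overall label from the four
aspect labels. At a node with label counts $(n_+, n_0, n_-)$ the Shannon
entropy (in bits) is $H = -\sum_\ell p_\ell \log_2 p_\ell$, and the split
criterion is information gain

$$
\mathrm{IG}(A) = H(\text{overall}) - \sum_{v}\frac{n_v}{n}
H(\text{overall} \mid A = v),
$$

maximized over the aspects not yet used on the path. Growth stops at pure
nodes, when no unused aspect remains, or — by default — when every
remaining aspect has zero gain; the `full_depth` flag restores literal
exhaustion of aspects, which can only append zero-gain splits and
therefore never changes the importance vector (a property the test suite
asserts).

The importance of aspect $A$ is the **normalized total information gain**:
the sum over all nodes splitting on $A$ of the node's gain weighted by the
fraction of training rows reaching that node, rescaled so the four
importances sum to one. The node-size weighting is the standard
impurity-decrease convention for tree feature importance; an unweighted
sum (also available via `weighted = FALSE`) would let tiny deep nodes
contribute as much as the root. Because the statistic is normalized, the
entropy base is immaterial to the ranking; bits are used as the ID3
convention.

Determinism is pinned down where the mathematics is silent: gain ties
break by the canonical aspect order (flavor accuracy, value, cloud
production, throat hit), leaf-majority ties break positive > neutral >
negative, and an aspect value unseen at a node during training routes to
that node's majority label at prediction time.

## Opinion-pair extraction

Opinions are (aspect noun, sentiment adjective) pairs. Extraction follows
three stages:

1. **Parsing.** Sentences are split, tokenized, part-of-speech tagged, and
   annotated with the two dependency relations extraction uses: the
   *adjectival modifier* pattern (an adjective directly modifying a noun,
   "a **great** **flavor**") and the *copular* pattern (a predicate
   adjective whose subject is a noun, "the **flavor** is **great**",
   relations nsubj + cop). The bundled parser is a deterministic
   dictionary-based tagger with positional dependency rules; it covers the
   synthetic templates' closed vocabulary (about 40 nouns and the lexicon's
   adjectives) exactly, and it tags unknown words as nouns, which is the
   conservative choice for term-frequency counting. Any statistical
   dependency parser can be substituted by producing the same
   `ParsedSentence` structure.
2. **Candidate selection.** Aspect words are nouns; nouns are ranked by
   corpus-wide token frequency and retained when their frequency is
   *strictly greater than* a threshold (default 20). The strictness
   matters: a noun at exactly the threshold never surfaces in a pair.
   Candidate nouns are then mapped to the four aspect categories through a
   keyword whitelist (flavor: flavor, juice, vape, taste, aftertaste;
   value: price, value, quality; cloud: vapor production, vapor, cloud
   production; throat: throat, hit, throat hit). The whitelist replaces a
   manual curation step with an explicit, user-editable configuration;
   two-token terms are matched as bigrams before unigrams, and bigrams are
   the longest terms supported.
3. **Polarity.** Each pair's adjective is looked up, case-insensitively,
   in a sentiment lexicon; absent words get polarity `unknown`. The
   bundled ~120-adjective seed lexicon covers the opinion vocabulary
   typical of this domain and makes the test suite hermetic; larger
   dictionaries load via `read_lexicon()`. Negation is deliberately **not**
   part of the default method — the extraction patterns carry no negation
   rule — but an optional `negation = TRUE` flag inverts polarity under a
   direct "not"/"never", clearly labeled an extension.

## Summarization

`review_sentiment_distribution()` tabulates discretized overall labels per
flavor category; `product_sentiment()` does the same over *products*
(mean overall rating, then the same discretizer); percentages everywhere
are $100\,c/n$ rounded **half-up** to two decimals, the convention that
reproduces printed review-site summary tables exactly from their raw
counts (e.g. `percent_of(18362, 27070)` is 67.83). Opinion summaries are
gated by ratings, not by lexicon polarity: under aspect scope, a pair
joins the positive (negative) summary of its category only if the source
review rated that aspect $\ge 4$ ($< 3$); the neutral band contributes to
neither side, and pairs whose term matches no category are excluded.
Under product scope the gate is the review's overall label and
uncategorized pairs are kept. `keyword_incidence()` counts *reviews*
containing a phrase (as a whole-token sequence), not occurrences,
matching how "posts containing" a term are reported.

## The synthetic-data generator

Real review corpora from e-liquid sites are not redistributable, so the
package generates corpora whose statistical structure matches what the
analysis assumes, with full ground truth:

* four aspect labels per review, i.i.d. from a prior of 0.6 / 0.2 / 0.2
  (positive / neutral / negative), mimicking the positive skew of real
  corpora (roughly two-thirds positive reviews);
* the overall label equals the label of **one aspect sampled with
  probability proportional to `aspect_weights`**, then replaced by a
  uniform label with probability `noise_rate`. This single-driver mixture
  was chosen over a noisy vote because it makes the weight→importance
  relationship transparent: with weight concentrated on one aspect the
  mutual information between that aspect and the overall label equals the
  label entropy, and weight rankings are recoverable as importance
  rankings (the suite requires recovery in at least 9 of 10 corpora at
  $n = 5000$ for weights 0.6 / 0.25 / 0.1 / 0.05 with 5% noise);
* labels become ratings uniform in their bands — positive $[4,5]$, neutral
  $[3,4)$, negative $[1,3)$ — so discretization inverts generation
  exactly;
* each aspect rating is blanked with probability `missing_rate` (default
  0.118, making about 60.6% of reviews complete, the fraction observed in
  real data); true labels are retained in the ground truth;
* text is assembled from templates: per non-neutral aspect label, with
  probability `phrase_rate`, a sentence plants an aspect keyword modified
  by a polarity-matched adjective in either adjectival ("Such a harsh
  throat hit overall.") or copular ("The throat hit is harsh.") order,
  plus one distractor sentence built from non-aspect nouns with no
  adjectives. Neutral labels plant nothing, as the polarity lexicon has no
  neutral adjectives. Flavor categories attach to products (drawn from
  proportions matching published per-flavor review counts, fruity and
  sweet dominant); reviews inherit their product's flavor.

Default corpus-shape parameters: 1000 reviews over ~300 products (about
three reviews per product), aspect weights defaulting to the published
normalized-gain profile (0.8912, 0.1022, 0.0049, 0.0017) so that default
corpora reproduce the qualitative finding that flavor accuracy and value
dominate, `phrase_rate` 0.7 (most but not all labeled aspects are
verbalized, as in real reviews), dates uniform over mid-2013 to end-2017.
Everything is deterministic given the seed, and the generator restores
the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: free-vocabulary text (no out-of-template
syntax, misspellings, sarcasm, or negated opinions), correlations among
aspect labels (they are independent by construction; real aspect ratings
correlate), review-length and user-identity structure, and time trends.
Extraction precision/recall of ≥ 0.95 on planted phrases validates the
pattern machinery, not parser performance on open-domain text.

## Numerical and design choices

* Entropy uses base 2; normalization makes the importance ranking
  base-invariant.
* Percentages round half-up (`round_half_up()`), implemented as
  `floor(100x + 0.5)/100`; base R's banker's rounding would differ at
  ties.
* Degenerate inputs: an empty labeled dataset (every review missing an
  aspect) is an explicit error ("no complete reviews after filtering");
  a single-leaf tree yields the all-zero importance vector rather than
  NaN; empty corpora produce empty, well-formed tables.
* Test problem sizes were chosen to exercise the statistics at stable
  scale while keeping the default suite fast: oracle equivalence on 20
  datasets of up to 50 rows (exact to 1e-12), parameter recovery on ten
  5000-review corpora, extraction recovery on a 1000-review corpus.

## Known limitations

Token frequency (not document frequency) drives candidate selection; the
two readings are both defensible and the choice is configurable only via
threshold. The bundled parser is intentionally minimal and will miss
long-range dependencies ("the flavor, though advertised as custard, is
great" links correctly only by accident of adjacency rules). No
deduplication or spam filtering is applied. Aspect-label independence in
the generator slightly *understates* the difficulty of importance
ranking on real data, where correlated aspects share information.
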