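---
title: "Lexicon-density classification of combat-exposure narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexicon-density classification of combat-exposure narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexdens)
```

## The problem

First-person web text — military blog posts in particular — carries clinically
interesting signal about combat exposure: concrete descriptions of events
(explosions, patrols, attacks) interleaved with the writer's emotional
reaction to them (fear, hope, feeling safe).  Reading thousands of posts to
find the relevant ones is expensive, and the text is noisy: expressive
spellings ("BOOM", "Boooom", "Bo-o-om"), abbreviations ("IED"), and informal
structure defeat tools tuned for clinical prose.

`lexdens` implements a deliberately transparent recognition pipeline for this
setting: a curated, category-structured lexicon is matched against stemmed
tokens, each document is scored by its *annotation density*, and a batch is
classified against the median density.  Every decision the classifier makes
can be traced to specific highlighted words.

## The model

For a document $d$ with $N_{wc}$ word tokens of which $N_{ann}$ are gazetteer
hits, the richness score is

$$ r_d = 100 \cdot \frac{N_{ann}}{N_{wc}} \quad (\text{percent}), $$

and a batch $D$ is classified transductively with the threshold
$\theta = \operatorname{median}\{ r_d : d \in D \}$:

$$ \hat{y}_d = \mathbf{1}[\, r_d > \theta \,]. $$

The inequality is strict, so with an odd batch the median document itself is
*not* automatically positive; ties at the threshold are classified
irrelevant.  The transductive threshold needs no training data, at the cost
that a document's label depends on the batch it is scored with; for scoring
single new documents, `predict()` (or the `--threshold` CLI flag) applies a
frozen threshold instead.

The assumptions are those of any bag-of-words method: word order,
negation and context are ignored (a post *denying* combat exposure that uses
the vocabulary will score high), and the lexicon is assumed to cover the
domain vocabulary.  Density is also length-sensitive in small documents: a
five-word post moves in 20-percentage-point steps.

## Preprocessing and noisy-text normalization

Tokenization keeps internal hyphens and apostrophes inside word tokens, so
"Bo-o-om" is one token; offsets are 0-based half-open character spans into
the raw text, which is never modified.  Word tokens are normalized by

1. lowercasing,
2. removing hyphens, and
3. collapsing any run of more than two identical letters to exactly two,

so "BOOM", "Boooom" and "Bo-o-om" all normalize to "boom", while legitimate
doubles ("attack") are preserved.  Normalization is idempotent.  Matching is
tiered: the matcher first tries the normalized form (and its stem); if that
misses, it tries the *run-of-one* fallback with every doubled letter
collapsed, which repairs elongations of originally-single letters
("saaafe" → "safe").

**Known limitation.** The run-of-one fallback collapses legitimate doubles
too, so an elongation applied to a word that also contains a genuine double
("attaaack": the fallback yields "atack") is not recovered.  In measurement
on corrupted lexicon surfaces this affects roughly a sixth of corrupted
tokens — concentrated in double-letter words (attack, mission, happen,
support) — which at a 20% corruption rate leaves annotation recall above
0.96.  We accept this rather than enumerate per-run collapse variants, whose
cost grows combinatorially and whose benefit is marginal.

Stop words are flagged (never deleted, so $N_{wc}$ is preserved) on the
normalized form *before* stemming, avoiding stemming artifacts of function
words.  The stop list is a conservative standard English list (articles,
prepositions, pronouns, auxiliaries, light verbs such as *go*, *do*,
*have*); content words the lexicon needs (*see*, *stop*, *fire*) are
deliberately absent.  Lexicon membership overrides stop status during
annotation, so a stop-listed word can still be highlighted if curated into
the lexicon.

## Stemming

The stemmer is the classic Porter suffix-stripping algorithm with one
widely used departure: the final-y rule rewrites *y* → *i* only when the *y*
is preceded by a consonant, so *deploy* stems to *deploy* (not *deploi*)
while *happy* still becomes *happi*.  The domain stems this produces —
*explos*, *vehicl*, *deton*, *secur*, *mission* — are exactly the forms the
lexicon stores.  The implementation is validated against a 50-word reference
vocabulary of published example transformations.

Two consequences of Porter mechanics matter for lexicon curation:

- stems need not be dictionary words, and some are not fixed points of the
  full algorithm ("explos" would lose its final *s* to the plural step);
  lexicon validation therefore checks that the stemmer *without its plural
  step* leaves each stored stem unchanged, which accepts true stemmer
  outputs while rejecting raw surface words ("explosion");
- *nervous* stems to *nervou* (the plural step strips the final *s* and the
  `-ous` rule requires a longer stem), so the stressful-emotion entry is
  stored as *nervou*.

## Indexing weights for lexicon construction

Candidate lexicon terms are ranked by a corpus-level TF\*IDF weight, one
weight per stem per corpus:

$$ \mathrm{tf}(s) = \frac{\text{count}(s)}{N}, \qquad
   \mathrm{idf}(s) = \log_{10}\frac{N}{\mathrm{df}(s)}, \qquad
   w(s) = \mathrm{tf}(s)\cdot\mathrm{idf}(s), $$

with $N$ the number of documents and $\mathrm{df}$ the document frequency.
Informal descriptions of TF\*IDF sometimes swap the two components'
definitions; we use the conventional reading, under which a stem in every
document has idf 0 and high weights go to frequent-but-concentrated stems.
Log base 10 is the default (idf of a stem in 1 of 10 documents is exactly 1)
and is configurable.  Candidate selection takes stems with weight *strictly
above* the cutoff, default 0.1.  Which surviving stems are genuinely
domain-relevant is a curator's judgement, not the tool's.

## The seed lexicon

The shipped lexicon organizes entries in a two-level tree: *CombatExposure*
(subcategories *Direct* — acting: fire, shot, attack, weapon, hit, patrol —
and *Indirect* — witnessing/context: explos, see, deton, bomb, mortar,
truck, vehicl, soldier, mission, stop, deploy, happen, boom) and *Emotion*
(*Protective*: hope, safe, secur, support; *Stressful*: scare, upset,
nervou).  The literal abbreviation "ied" is a surface variant of the *bomb*
entry, matched on the normalized surface without stemming.  The printed
ranked stem list the exposure side derives from contains nineteen stems;
with *boom* the exposure side reaches twenty entries.  The Direct/Indirect
split beyond the obvious cases is a curator annotation; classification only
uses top-level counts, so the split affects reporting, not decisions.
Each stem belongs to exactly one leaf category, which keeps annotation
deterministic; ambiguous words must be split by the curator into distinct
surface variants.

Per-top-category densities (exposure-only and emotion-only counts) are
computed and reported by `summary()` and in evaluation reports, but the
decision rule uses the total density only.

## Evaluation

Against expert labels the package reports the confusion matrix and

$$ P = \frac{TP}{TP+FP}, \qquad R = \frac{TP}{TP+FN}, \qquad
   F = \frac{2PR}{P+R}, $$

with zero-denominator cases reported as `NA` with a warning, never silently
as 0.  The packaged `pilot_scores()` fixture — twenty per-document densities
with expert judgements from the pilot evaluation of this design — reproduces
threshold 4.95%, confusion (9, 1, 7, 3), $P = 0.90$, $R = 0.75$, $F = 0.82$,
and is the primary regression test.

Display rounding is two decimals, half away from zero; all internal
arithmetic keeps full precision and rounding happens only at reporting.

## The synthetic-corpus generator

The original blog corpus cannot be redistributed, so the test suite runs on
generated corpora that emulate its *statistical* structure:

| parameter     | default | meaning                                          |
|---------------|---------|--------------------------------------------------|
| `n_pos`, `n_neg` | 50, 50 | documents per class                            |
| `len_mean`, `len_sd` | 150, 30 | words per document (normal, floored at 5) |
| `density_pos` | 0.10    | P(token is a lexicon draw) in positives          |
| `density_neg` | 0.01    | same in controls                                 |
| `noise_rate`  | 0.10    | P(corruption) per lexicon token                  |
| `seed`        | 1       | full determinism; the caller's RNG is untouched  |

Each token is independently a lexicon draw (an entry inflected through a
small suffix table — only forms that stem back to their entry are kept, so
generated surfaces genuinely exercise the stemming path) or a background
word from a fixed 500-word neutral vocabulary verified stem-disjoint from
the lexicon, so background tokens can never be hits.  Corruptions emulate
expressive blog orthography: vowel elongation ("boooom") or hyphenated
stutter ("bo-o-om").  Document lengths around 150 words reflect short
blog-post narratives; the 10%-vs-1% densities encode the qualitative
observation that exposure posts are rich in domain vocabulary while ordinary
military-life posts are not, with enough binomial separation at length 150
that the median threshold sits cleanly between the classes.

What the generator does *not* emulate: narrative fluency and word order
(irrelevant to a bag-of-words decision rule), topical background drift,
video-game war stories and other adversarial confounds, misspellings beyond
elongation/hyphenation, and document-level correlation of vocabulary.
Passing the synthetic-recovery test therefore shows the pipeline's machinery
(normalization, stemming, matching, thresholding) recovers a known density
separation; it does not certify performance on real blogs.

## Problem sizes in the test suite

The suite validates the indexing statistics against a brute-force recount on
corpora up to 5 documents × 20 tokens, normalization idempotence on 10,000
random strings, and end-to-end synthetic recovery (F1 ≥ 0.95) on five seeded
corpora of 100 documents × ~150 words — sizes at which the brute-force
oracles are exact and the binomial separation argument above applies.

## Degenerate inputs and numerical choices

- Empty documents (no word tokens) score ratio 0 with a warning.
- Empty corpora, empty batches and threshold derivation from zero scores are
  validation errors, not silent defaults.
- Invalid UTF-8 is repaired with replacement characters and logged per
  document; ingest never modifies valid text.
- Weight ties in the TF\*IDF ranking break lexicographically by stem, making
  exports deterministic.
- The generator restores the caller's RNG state, so corpus generation is
  reproducible without side effects on the session.

## Limitations

Beyond the bag-of-words assumptions above: the lexicon is small and
hand-curated (a reconstruction of the published seed vocabulary, not the
full 263-stem list, which was never published); abbreviation *misspellings*
("IOD" for "IED") are out of scope — only explicit surface variants are
matched; and the transductive threshold assumes the batch mixes relevant and
irrelevant documents in roughly comparable numbers, since the median of a
nearly-pure batch separates nothing.
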