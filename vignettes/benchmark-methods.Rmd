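---
title: "Methods: multilingual LLM differential-diagnosis benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilingual LLM differential-diagnosis benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the measurement model

Rare-disease differential diagnosis is a ranked-retrieval task: given a
phenotypic description of one patient, a model returns an ordered list of
candidate diseases, and the quantity of interest is the rank at which the
true diagnosis appears. `lingodx` measures this across prompt languages
while holding everything else fixed: the same structured case is rendered
into parallel prompts in ten languages, every reply is requested in
English, and scoring is language-blind by construction (it sees only
grounded ontology identifiers and the case diagnosis).

Per language, cases are partitioned into Top-1 / Top-3 / Top-10
(cumulative), *beyond-10* (correct only after rank 10), *not ranked* (no
correct candidate in the reply; grounding failures land here), and *no
diagnosis* (the reply could not be parsed as a differential at all —
refusal). Conservation
`top10 + beyond10 + not_ranked + no_diagnosis = n_total` is enforced by
the aggregation itself and re-checked on every emitted table. Reported
frequencies are `100 * topN / (n_total - no_diagnosis)` by default; the
all-cases denominator is always emitted alongside because published
abstracts do not always say which convention they use (for the English row
of the count tables shipped here both give the same one-decimal values).
Percentages are rounded half-up to one decimal, the precision at which
such tables are printed.

## Subtype-equivalence rollup

Disease ontologies place genetic subtypes (e.g. "X syndrome type 2")
under a clinical grouping term ("X syndrome"). A reply naming either the
grouping or any sibling subtype of the true diagnosis is clinically
correct, so the equivalence class of a diagnosis is: the diagnosis, its
descendants, and — for each parent that qualifies as a grouping term —
that parent plus all of its descendants. A parent qualifies when it is
explicitly configured as a grouping term or (default heuristic) when its
label is a prefix of the diagnosis label. Ancestors never enter the class
any other way: crediting "syndromic disease" for everything would be
meaningless. Descendants of the diagnosis always count, because a *more*
specific correct answer is still correct.

## Grounding

Free-text candidates are matched by exact lookup after normalization
(Unicode NFKC, case folding, typographic dash/apostrophe/quote mapping,
whitespace collapse, surrounding-punctuation strip). We deliberately do
not do fuzzy matching by default: the benchmark tolerates grounding
failures (reported as a per-candidate rate) rather than risk silently
crediting a wrong disease; a token-similarity mode exists behind the
index but is off by default. One terminal parenthetical ("(FBN1)",
"(OMIM 154700)") is stripped before lookup; if the stripped form misses,
the verbatim form is retried, which keeps behaviour deterministic for
labels that themselves contain parentheses. Index collisions are resolved
deterministically — primary label beats synonym, then smallest term id —
and logged. Replies in a non-Latin script (a model ignoring the
English-reply instruction) simply fail lookup in the English-label index
and are counted as grounding failures; this mirrors the behaviour the
benchmark attributes to models with weaker instruction-following in CJK
languages.

## Prompt templating

A template pack is pure data (JSON): constant header, per-sex and
age-class subject frames, observed/excluded/onset sentence frames, list
punctuation, and age-phrase rules. Adding a language is adding a file.
Choices the source material leaves open, fixed here:

- **Age truncation.** Mixed-unit durations truncate to the largest unit
  (`P2Y3M` renders as the 2-year phrase) — ages in clinical vignettes are
  conventionally rounded down.
- **Onset grouping.** Observed features sharing an onset value are grouped
  into one onset sentence (first-appearance order); features without onset
  form a single "presented with" sentence; excluded features form one
  exclusion sentence. Sentence order: subject, onset groups, remaining
  observed, excluded.
- **Unknown sex** renders a neutral noun; a large fraction of real cases
  have unspecified sex, so the frame must exist in every pack.
- **Punctuation** is pack-local (Japanese and Chinese use "、"), so
  rendered text is byte-stable per language.
- Only primary translated labels are used in rendering; translated
  synonyms are carried in the table but unused, pending a stated use.

The renderer guarantees: the term manifest (ids + observed/excluded
status) is identical across languages for the same case; every manifest
label is a substring of the text; the diagnosis id/label and any genetic
information never appear (checked by substring scan in tests); rendering
is deterministic.

## The mock backend

Live model calls are out of scope; the mock backend is the test double
that makes the pipeline measurable. It is a pure function of
`(profile, seed, case_id, language)` — per-prompt RNG streams are derived
by a stable string hash, so any subset of a run, in any order, reproduces
byte-identically (mimicking independent API calls). The profile gives
per-rank probabilities for the correct diagnosis, a refusal probability,
a per-line garble probability (ungroundable nonsense), a subtype-swap
probability (a sibling subtype's label replaces the correct one — which
the equivalence rollup must absorb), and an ignore-English probability
(the diagnosis is emitted in the prompt language and should then fail
grounding). Distractor lines are sampled from disease labels outside the
diagnosis's whole credit set (ancestors, descendants, sibling subtypes),
so no credit can leak through distractors. Because the backend emits the
*correct* label when the profile says so, it must know each case's
diagnosis; since the diagnosis is deliberately absent from the prompt,
the constructor takes a `case_id -> diagnosis` map alongside the ontology
— a deliberate extension of the minimal backend contract.

Garble may hit any line, including the correct one; profiles used for
rank-recovery checks therefore set garble to zero, and the garble
invariant test expects the injected rate exactly.

## Synthetic world

The generator states one fixed world rather than tunable realism: Poisson
mean 14 phenotype terms per case (the corpus average), sex probabilities
proportional to the printed 1590/1826/1500 female/male/unspecified
triple, 15% excluded features, onset on half of observed features,
subject age recorded for 80% of cases, 2–6 genetic subtypes per clinical
grouping disease, and per-disease pools of 25 phenotype terms from which
cases draw 80% of their features (20% uniform noise). Pool membership is
shared across sibling subtypes so subtype swaps stay phenotypically
coherent. Disease names are seeded pseudo-words ("Bodaki syndrome type
2"), translations are tagged pseudo-localizations (`de:`, `仮:` …):
linguistic realism is irrelevant to every invariant tested, and a green
test here establishes *plumbing and accounting* correctness — parsing,
rendering parity, grounding, rollup, aggregation — not clinical validity
or anything about real model accuracy. Features real data has that this
world does not: phenotype-frequency structure within a disease,
correlated features, onset consistent with subject age, multilingual
label quality.

## Statistics

The Kruskal–Wallis H statistic is computed from the tie-corrected
rank-sum formula and the chi-square upper tail with k−1 degrees of
freedom; tests require agreement with an independent reference
implementation to 1e-9 over random sweeps. The ordinal coding — this
package's convention, since the source tables do not fix one — is the
per-case correct rank with unranked cases coded 11 (one worse than any
credited rank) and refusals excluded. The published H values for the real
runs are therefore not claimed as reproducible targets: they depend on
per-case data and a coding choice not available here.

## Numerical and degenerate-input choices

- Half-up rounding (with a 1e-9 epsilon against binary representation) for
  all reported percentages; base R's half-to-even would flip printed
  digits.
- Kruskal–Wallis on all-identical pooled values is an error (tie
  correction degenerates), not an NaN.
- A case with all features excluded is rejected at construction: a
  vignette with no findings is untestable.
- Empty replies, whitespace replies, and dispatch failures all score as
  refusals; refusal is a value, never an exception.
- `beyond10` is tracked separately and only folded into "not ranked" when
  emitting published-style tables, so a hypothetical correct answer past
  rank 10 is never silently discarded.

## Known limitations

Exact-match grounding only (by default); English-only grounding index;
template frames are pre-inflected by pack authors (no grammar engine);
the shipped non-English packs are fixture-grade translations; onset ages
in synthetic cases may exceed the subject's age; live-API adapters are
interface-only and untested against real endpoints.
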