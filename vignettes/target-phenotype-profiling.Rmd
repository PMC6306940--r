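---
title: "Target-level phenotype profiling from adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-level phenotype profiling from adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetAE)
```

## The idea

Spontaneous adverse-event (AE) reporting systems collect, for millions of
patients, the drugs a patient took, the indications they were treated for,
the reactions that followed, and a small set of clinical outcomes.  Because
drugs act by perturbing protein function, each case report can be read as
an uncontrolled, noisy perturbation experiment on a human: if the drugs in
a case are mapped to their molecular targets, co-occurrence statistics
between *targets* and *reactions* can be computed exactly as
pharmacovigilance has long computed them between drugs and reactions.
`targetAE` implements that drug-centric integration pipeline and its
statistical characterization end to end:

1. **Name normalization** — verbatim drug-mention strings are matched to a
   synonym dictionary through a stepwise procedure (exact, token-part,
   bounded edit distance), with a blacklist of irrelevant tokens.
2. **Molecular expansion** — mapped drugs are expanded per case to
   targets, metabolizing enzymes, carriers, transporters, pathways and ATC
   classes.
3. **Disproportionality** — for any (entity, event) pair a 2×2
   contingency table is built over cases and characterized by the
   proportional reporting ratio, Fisher's exact test and
   Benjamini–Hochberg q-values.
4. **Comparative utilities** — temporal slices for prospective
   prediction, cohort outcome contrasts ("virtual perturbation
   experiments"), mechanism-stratified (agonist vs antagonist) profiles
   and a direct-vs-indirect benchmark.

## The statistic

For an entity $X$ (drug, target, ATC class, pathway) and an event $E$
(reaction, indication or outcome, optionally rolled up the phenotype
hierarchy), cases partition as

|            | $E$ | not $E$ |
|------------|-----|---------|
| $X$        | $a$ | $b$     |
| not $X$    | $c$ | $d$     |

and the proportional reporting ratio is

$$\mathrm{PRR} = \frac{a(c+d)}{c(a+b)}
             = \frac{a/(a+b)}{c/(c+d)},$$

the event's reporting proportion among entity-exposed cases relative to
the unexposed remainder.  No continuity correction is applied and no
confidence interval is reported; significance is carried by Fisher's exact
test (two-sided by default, minimum-likelihood rule) and by q-values over
the screen or profile at hand.  Degenerate tables ($c = 0$ or $a+b = 0$)
raise by default; bulk screens use the permissive form (`Inf`/`NaN`)
because such cells are expected there.

An association is **supported** when $a \ge 10$, **strong** when
$\mathrm{PRR} \ge 2$ and **significant** when $q < 0.05$; an entity is
profiled at all only when linked to at least 500 cases.  These defaults
mirror the reporting conventions of large published target-phenotype
screens and live in one place, `signal_filter()`.

## Vocabulary model

Phenotypes live in a 4-level hierarchy: level 1 is the broadest
(system-organ-class-like), level 4 the most specific
(preferred-term-like).  Rolling specific terms up to level 2 or 3
compensates for near-synonymous sibling leaves (e.g. several "coronary
artery ..." terms under one class).  A fifth, verbatim-level tier is
deliberately not modeled.  Outcome codes are the closed FAERS 7-set
`DE, LT, HO, DS, CA, RI, OT`.

## Name mapping choices

* "Differs by more than 5 characters" is implemented as Levenshtein edit
  distance > 5, computed on *normalized* strings (case-folded,
  punctuation collapsed).  Distance on normalized forms is the
  conservative reading: surface decorations ("®", hyphens, case) should
  not consume the edit budget.
* The token-part phase stands in for the unspecified "regular
  expressions" step: a synonym of at least 4 characters matching a whole
  token subsequence of the mention counts as a part match, which handles
  dose-form phrases ("TYLENOL 500MG TABLET") without opening the door to
  spurious short-substring hits.
* Ties at minimal edit distance return all tied drugs and are marked
  ambiguous; ambiguous fuzzy matches are excluded from molecular
  expansion by default (`include_ambiguous = FALSE`) because a wrong
  target attribution is worse than a lost case.
* Lump categories ("vitamins") are a blacklist concern, not a class
  expansion: the data model has no sound way to pick a member.

## Exposure semantics

Exposure is case-level presence: a case is exposed to a target if any of
its mapped drugs links to it with role `target`.  There is no dose,
duration or suspect/concomitant weighting — the source data model has no
reliable versions of them.  Cases whose mentions all failed to map stay in
the corpus; they still inform the $c$ and $d$ cells.  The clean-target
filter (`clean_targets()`) removes proteins that are also listed as
metabolizing enzymes, carriers or transporters of any drug, because their
co-mention with a phenotype may reflect pharmacokinetics rather than
pharmacology.

For mechanism-stratified profiles, a case engaged by both an agonist and
an antagonist of the same target is a conflict and is excluded from both
sides, as are cases engaged only with action `unknown`; each side's
comparator is the never-exposed remainder, so each side's $N$ is its
partition size.

## Multiple testing

The q-value reference method is Benjamini–Hochberg (step-up, $\pi_0 = 1$),
which is the conservative special case of the Storey estimator; Storey's
$\hat\pi_0 = \min(1, \overline{\mathbb{1}[p>0.5]}/0.5)$ is available via
`qvalues(p, method = "storey")`.  q-values are always computed **within**
one `screen_all()` or `profile_entity()` call, never across calls: the
same pair can legitimately carry different q-values in a level-2 screen
and in a single-target profile, because the family of tests differs.

## The synthetic world

`generator_config()` states the simulated world once; its defaults are the
conditions the validation properties are defined on and are not tuning
knobs:

| parameter | default | meaning |
|---|---|---|
| `n_cases` | 50,000 | corpus size |
| `n_drugs`, `n_proteins` | 60, 80 | dictionary and proteome size |
| `n_reaction_leaves` | 64 | specific (level-4) reaction terms |
| `background_reaction_prob` | 0.01 | per-(case, leaf) background rate |
| `n_planted`, `planted_multiplier` | 10, 5 | planted protein-reaction effects |
| `typo_prob`, `max_edits` | 0.2, 2 | mention corruption |
| `blacklist_mention_prob` | 0.02 | "UNKNOWN"/"UNK" injection |
| `non_target_role_frac` | 0.3 | proteins failing the clean filter |
| `date_range` | 2000–2016 | uniform report dates, 2% undated |

Planted effects act at the protein level — any drug hitting a planted
protein raises the reaction's probability to
$\min(1, \text{multiplier} \times \text{background})$ — matching the
target-centric thesis being tested.  Dictionary names are generated
pairwise ≥ 5 edits apart, so ≤ 2-edit corruption can never make the
intended drug ambiguous; this is what makes the ≥ 95 % intended-mapping
property a clean test of the matcher rather than of luck.  Two derived
RNG substreams (seed for the world, seed + 1 for the cases) keep
`generate_world()` and `generate_cases()` independently reproducible.

What the generator does **not** emulate: reporting-rate dynamics over
time, stimulated reporting after label changes, duplicate/follow-up
reports (input is assumed pre-deduplicated), drug–drug interaction
effects, and real MedDRA/ATC/DrugBank content.  A green planted-recovery
test therefore establishes that the pipeline recovers effects of the
stated size under the stated noise — not that it reproduces any
real-world dataset's headline counts, which require the proprietary
source corpora.

## Cohort contrasts

`compare_outcome()` contrasts one outcome's rate between two disjoint
cohorts and reports rates (one-decimal percent at presentation, full
precision internally), the risk ratio and a Fisher exact p-value.  The
worked example reproduced in the tests: deaths under beta-blockade in a
skin-cancer population, 241/1308 (18.4 %) vs 4059/17,177 (23.6 %),
p = 0.000012.  The published figure's sidedness is unstated; the
two-sided default reproduces it at the printed precision, and that
convention is recorded here.  No matching or adjustment is attempted —
the primitive is a raw-rate contrast.

## Direct vs indirect benchmarking

For a known protein-effect pair, the **direct** method scores the
case-level protein-vs-effect table; the **indirect** method (representing
drug-centric annotation transfer) counts *drugs* — targeting vs
co-reported — in a drug-level 2×2, plus the max/mean/min of per-drug
case-level PRRs.  "Recapitulated" means passing the same
supported∧strong∧significant flags in the respective method's table; the
criterion is not defined numerically in the source methodology, so the
package states it explicitly and applies it symmetrically.  When an
effect is carried by a minority of a target's drugs, the direct method
keeps the signal while the drug-level table dilutes it — the tests
construct exactly such worlds.  Effect-term selection prefers the most
specific synonym and falls back to the broader one when the specific term
co-occurs in fewer than `min_cooccurrence` cases.

## Numerical notes and edge cases

* `fisher_exact()` sums `dhyper()` over the support; the two-sided rule
  counts tables with probability ≤ observed × (1 + 1e-7), the standard
  guard against ties lost to floating point.  It matches full
  enumeration (via `lchoose`) to 1e-12 for N ≤ 40 in the tests.
* `qvalues()` validates p ∈ [0, 1] and is exactly the step-up definition;
  monotonicity is asserted property-style.
* Profile ranking: flagged records first, then PRR descending, ties by
  `a` descending then `event_id` — fully deterministic.
* Dateless cases are retained everywhere except temporal slices and date
  criteria, which they never satisfy.
* Duplicate case ids, orphan hierarchy terms, equal-level parents and
  unknown outcome codes are hard errors at load, not warnings.

## Known limitations

Confounding by indication, polypharmacy correlations and reporting biases
are inherent to the data model and are not adjusted for; signals are
screening hypotheses, not causal estimates.  Multi-report deduplication,
FAERS role codes (suspect vs concomitant) and dose/route parsing are out
of scope.  The drug-name matcher is dictionary-bound: a brand name absent
from the dictionary cannot be resolved by ingredient decomposition.
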