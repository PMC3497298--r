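---
title: "Triage of unknown-function structure entries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of unknown-function structure entries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbtriage)
```

## The problem

Structure repositories hold thousands of coordinate entries deposited under
an "unknown function" classification. Many of these are no longer truly
uncharacterized: the matching sequence-database record has since acquired
curated annotation, or homologs of known function have become detectable at
the sequence or fold level — often because the homolog was deposited *after*
the query structure, so the original depositors could not have cited it.
`pdbtriage` implements a deterministic four-stage triage that separates the
genuinely uncharacterized entries ("true unknowns") from re-annotation
candidates, and produces an auditable funnel report in which every count and
percentage is recomputed from the per-entry verdicts.

The pipeline is a rule system, not a statistical estimator: given the same
inputs and configuration it always produces the same output, and each rule is
small enough to be checked independently (the test suite contains a
straight-line re-implementation of all rules that must agree label-for-label
on small corpora).

## The four stages

**Stage 1 — annotation sufficiency.** Each entry's mapped sequence-database
record is inspected. The record counts as *sufficient characterization* when
it carries a function description, a catalytic activity, an EC number, or an
informative Gene Ontology profile: at least `min_go_terms` terms (default 3),
unless *all* terms are from the cellular-component ontology or *all* term
names end in "binding" — either exception voids the profile, because pure
localization or pure binding vocabulary carries no specific functional
signal. A record whose own name is uninformative (contains "uncharacterized",
"putative", "unknown", "predicted", "unnamed", "probable" or "hypothetical"
as a whole word) is an *uncharacterized equivalent* regardless of its other
fields: its annotations were never vetted against a named function.
Sufficient entries leave the funnel; everything else proceeds.

Name matching is whole-word on alphanumeric token boundaries, so "probable"
matches but "probability" does not, and "ATP-ase" splits into tokens `atp`,
`ase` (neither blacklisted). When an entry maps to several records the
default policy is disjunctive (`any-sufficient`): one sufficient record makes
the entry sufficient, and otherwise the first resolvable record decides; a
strict `first` policy is available.

**Stage 2 — sequence evidence.** Tabular sequence-search hits are filtered
with GO-domain-specific percent-identity cutoffs: a hit supports a domain
only when the identity *strictly* exceeds 40% (biological process), 50%
(molecular function) or 60% (cellular component) — identity levels at which
randomly selected protein pairs share roughly 70% of their GO terms. For the
molecular-function domain, hits whose MF terms all end in "binding" are
excluded on top. Hits to subjects with uninformative names are discarded
outright. A query is *significant* when at least one characterized hit
supports at least one domain; significance per domain is combined
disjunctively ("any domain"), since the cutoffs come with no aggregation
rule and a single kinase hit above 40% is treated as evidence. Queries
partition into five classes: significant with all hits characterized,
significant with a mix of characterized and discarded hits, discarded-only,
sub-threshold (characterized hits only, none supporting), and no hits. The
e-value is carried through but never filtered on: identity is the only
significance statistic, and inventing an additional filter would change the
published operating point.

**Stage 3 — structural evidence.** Structural alignment hits are admissible
only when the subject is outside the initial corpus (self-hits carry no new
information), is not classified "unknown function", and has a classification
header and name that pass the same blacklist. The outcome is the Z-score
band of the *best* admissible hit: strictly above 20 is a definite homolog,
strictly below 8 probably unrelated, and the closed interval [8, 20]
(including both boundary values, per the strict readings of "more than 20"
and "less than 8") a probable homolog. Only definite homologs remove an
entry from the true-unknown pool; probable homologs are reported but not
acted on. Classification uses the best hit, not a vote, because the Z-score
is a per-alignment statistic and the question is whether *any* definite
homolog of known function exists. Ties on Z resolve to the lexicographically
smallest subject ID, for determinism.

**Stage 4 — provenance dating.** For every entry with retained evidence the
earliest evidence date (integration dates of supporting sequence hits,
deposition date of the definite structural best hit) is compared with the
entry's own deposition date. Lags are whole years, `floor(days / 365.25)`,
which reproduces both reference gaps (Aug 2000 to Mar 2011 is 10 years,
Feb 2002 to Apr 2011 is 9). Evidence available on the deposition day itself
counts as *not* postdating — it could in principle have been cited. Two
metadata discrepancy flags are computed from the entry's own strings:
`NAME_VS_CLASS` (header says "unknown function" but the molecule name names
a function) and `CLASS_VS_NAME` (header names a function but the molecule
name is uninformative). "Names a function" is mechanized as: informative per
the blacklist *and* containing a token matching the function vocabulary
(default: tokens ending in "ase", which covers kinase, ligase, synthase,
ATP-ase, ...; configurable). The original check was manual; this captures
its clearest signal and nothing more.

The per-channel postdating fractions default to a per-*query* denominator
(each query contributes once via its earliest evidence date); a
per-*alignment* mode is available (`date_denominator = "alignments"`)
because the published convention is ambiguous between the two. Neither
fraction is asserted against any external value.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_go_terms` | 3 | terms | minimum GO profile size for sufficiency |
| `blacklist` | 7 words | — | uninformative-name keywords |
| `accession_policy` | any-sufficient | — | multi-accession combination |
| `cutoffs` (BP/MF/CC) | 40 / 50 / 60 | % identity | strict per-domain thresholds |
| `bands` | 20 / 8 | Z-score | definite / probable band edges |
| `date_denominator` | queries | — | postdating fraction convention |
| `function_vocabulary` | `ase$` | regex on tokens | "names a function" test |

The default `min_go_terms = 3` deserves a note: the source material states
both "at least 3" and "more than three" GO terms. We adopt ≥ 3 because the
all-three-CC / all-three-binding exception clauses only make sense if
exactly-3 profiles can qualify at all; the parameter is configurable for
users who prefer the stricter reading.

## The synthetic corpus generator

No accessions are distributed with the package; every corpus is generated by
code. `corpus_spec()` fixes the class structure — how many entries fall into
each annotation status, how the forwarded entries split across the five
sequence classes, how the structure-stage entries split across the four
Z-bands — and `generate_corpus()` constructs entry metadata, annotation
records and hit tables such that the pipeline reproduces those counts
*exactly*. Sufficient records rotate through the four evidence routes (GO
profile, function text, EC number, catalytic activity); insufficient records
rotate through the failure modes (no terms, too few terms, all-CC,
all-binding); significant hits draw identities uniformly in
(cutoff + 1, 95] and sub-threshold hits strictly below their cutoffs, with a
one-point margin so rounding can never cross a boundary — except for the
deliberately injected boundary records (identities exactly 40 / 50 / 60,
Z-scores exactly 20 / 8 / 7.9) placed in the non-significant pools to police
the strict inequalities. Inadmissible decoy hits (subjects classified
"unknown function", or subjects inside the corpus itself) are planted with
Z-scores *above* the best admissible hit to verify that admissibility
filtering, not score ranking, decides.

`printed_funnel_spec()` is the fixed reference specification: 2549 entries
split 868 / 520 / 1097 / 64 by annotation status, the 1681 forwarded queries
split 299 / 79 / 335 / 647 / 321 across the sequence classes, and the 1303
structure-stage queries split 219 / 381 / 703 across definite / probable /
rest. The 703 residual is divided 352 / 351 between unrelated and no-hits;
the split is arbitrary (the funnel only ever reports the combined number)
and fixed once for determinism. The two sequence/structure residuals (321
and 703) are themselves derived from the published stage totals rather than
printed anywhere, so the generator treats them as exact remainders.

Deposition dates are drawn uniformly in the window 1999-12-13 to 2012-05-16
(the corpus acquisition era), and evidence dates are placed strictly before
or after their query's date so that the per-channel postdating fractions
(defaults 43.65% for the sequence channel, 69.10% for the structural
channel) hold by construction, rounded to whole queries. Offsets are 30 to
3650 days, giving lags up to ten years and never an equal-date tie.

What the generator does *not* emulate: real sequence content (no stage
consumes residues, so none is generated), GO-graph structure (terms are flat
labels, exactly as the triage rules treat them), realistic hit-count
distributions, or correlated annotation errors. Passing tests on generated
corpora therefore demonstrate that the *rules* are implemented exactly, not
that the rules are robust to the messiness of live database snapshots — the
latter is a property of the rules themselves, not of this implementation.

## Numerical and degenerate-input choices

* Percentages are computed at report time from integer counts, rounded to
  two decimals half-away-from-zero. One published pair is arithmetically
  inconsistent (868 of 2549 printed as both 34.53% and 34.05%); the report
  yields the consistent 34.05.
* All thresholds are strict inequalities; boundary values (identity exactly
  at a cutoff, Z exactly 20 or 8) are classified on the non-significant
  side, and the generator plants such records so the tests would catch an
  off-by-one.
* Empty names are uninformative by definition; a subject with no GO terms
  supports no domain; an empty hit table is `NO_HITS`, distinct from
  "hits that were all discarded".
* Ties on Z-score resolve by subject ID; ID lists in reports are sorted
  lexicographically; rerunning the pipeline on identical inputs is
  byte-identical. There is no randomness anywhere in the pipeline proper —
  only the generator consumes a seed.
* Readers validate eagerly and report offending line numbers; hits whose
  subject metadata is missing are excluded with a record of what was dropped
  (strict mode turns this into an error).

## Problem sizes

The reference corpus (2549 entries, ~1500 sequence hit rows, ~1200
structural hit rows, ~5400 annotation records) generates in a few seconds
and triages in a few seconds more; the property-based suite runs a hundred
corpora of up to 500 entries. These sizes exercise every rule and boundary
case while keeping the full suite comfortably fast.

## Known limitations

* PDB-to-sequence-database mapping is taken from the input file as given;
  no remapping or chain-level resolution is attempted beyond stripping chain
  suffixes from query IDs.
* GO terms are flat labels: no ancestor closure, so a profile of three very
  general terms counts the same as three specific ones.
* Evidence codes are parsed and carried but ignored by the sufficiency
  decision: computationally inferred (IEA) terms count like curated ones.
  The reliability concern is real, but weighting evidence codes would
  change the published operating point.
* The literature channel (primary citations describing a function that the
  metadata lacks) is out of scope; only the two metadata strings are
  cross-checked.
* The per-channel postdating fractions depend on a denominator convention
  that cannot be pinned down externally; both conventions are implemented
  and the choice is explicit in the control object.

## A worked example

```{r example}
spec <- corpus_spec(n_entries = 40,
                    statuses = c(10, 10, 12, 8),
                    seq_classes = c(6, 2, 7, 9, 6),
                    struct_classes = c(5, 6, 6, 5),
                    seed = 11)
corpus <- generate_corpus(spec)
fit <- triage_corpus(corpus$entries, corpus$annotations,
                     corpus$sequence_hits, corpus$structure_hits)
fit
summary(fit)
```

The funnel counts equal the specification's by construction; the two
provenance fractions reflect the generator's postdating defaults rounded to
whole queries.
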