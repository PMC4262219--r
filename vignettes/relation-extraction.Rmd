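---
title: "Trigger-driven pattern-based event extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-driven pattern-based event extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrex)
```

# The extraction model

patrex extracts biomedical events — phosphorylation, gene expression,
transcription, protein catabolism, localization, binding — from text whose
entity mentions (genes and gene products, GGPs) are already annotated. The
system is entirely rule-based and requires no annotated training corpus:
its only task-specific input is a *trigger specification* per trigger verb
root, for example

```
trigger: phosphorylate
relation: Phosphorylation
frame: NP0/NP1
type: NP0 = GGP
type: NP1 = GGP|protein_part
role: NP0 = agent
role: NP1 = theme
direction: directional
affixes: -ion, under-, hyper-
```

Three linguistic generalizations do the rest of the work.

**Argument realization.** A verb's semantic arguments surface in a limited
set of syntactic positions, and the nominalizations and adjectival
conversions of that verb realize the same arguments in parallel positions
("JNK phosphorylates NFAT4", "NFAT4 is phosphorylated by JNK",
"phosphorylation of NFAT4 by JNK", "phosphorylated NFAT4"). patrex encodes
these positions as a fixed inventory of 26 *pattern templates* — 7 verbal,
9 nominal, 4 adjectival, 6 null-argument — each an abstract element
sequence with one trigger placeholder and at most one argument
placeholder. Capturing one argument at a time keeps the inventory small;
pairs sharing a trigger occurrence are combined into events afterwards.
The *frame* named in the specification (transitive `NP0/NP1`, intransitive
agentive `NP0`, unaccusative `NP1`) selects the compatible templates; only
transitive frames receive passive templates, and non-directional triggers
("bind": swapping the participants preserves meaning) additionally receive
the reciprocal/with/to/between templates.

**Surface-form derivation.** From each root, all trigger surface forms are
derived by standard English inflection rules (e-drop before vowel-initial
suffixes, y→i, consonant doubling) composed with the spec's affix
descriptors (`-ion`, `-age`, `-ment`, `over-`, `co-`, ...). True stem
changes (bind→bound, transcribe→transcription, degrade→degradation,
proteolyse→proteolysis) live in an explicit exception lexicon, which takes
the place of the interactive user confirmation a deployed system would
use. Nominalizations that denote entities rather than processes
("transcript", "product") are derivable but flagged and excluded from
pattern generation: only process nominals head event-denoting noun
phrases.

**Tree-pattern matching with head selection.** Templates are instantiated
into lexico-syntactic patterns by substituting a surface form for the
trigger placeholder, and compiled into a small tgrep-style tree-pattern
language (`<` child, `<<` descendant, `<:` sole child, `$` following
sibling, `.` adjacency, `!` negation, `and` conjunction, `=name`
captures). A raw match is then validated structurally:

* the trigger must be the *head of its consecutive verb group* — the last
  main verb reached by descending through auxiliaries, modals,
  infinitival *to* and raising carriers ("known", "shown", "likely"), so
  "is known to bind" is headed by "bind";
* voice must agree with the template (a passive head is a past participle
  with a *be* auxiliary in its chain);
* a nominal trigger must be the head noun of its noun phrase (rightmost
  nominal descent, ignoring parenthetical material);
* adjuncts are skipped by construction: arguments are located as
  constituents of the clause, so adverbials and intervening prepositional
  phrases ("abundantly expressed X in the cytoplasm") do not block a
  match.

# Sentence simplification

Rather than multiplying patterns to cover complex sentences, complex
constructs are detected and the sentence is rewritten into simpler
variants, each carrying a character-level offset map back to the original
so extracted spans are always reported in original coordinates:

* **coordination** (noun, noun-phrase, verb, verb-phrase, clause): one
  variant per conjunct;
* **relative clauses** (full, introduced by which/who/that; reduced,
  starting with a participle): a clause-removed variant plus a new
  sentence "referent + clause" (a reduced passive clause receives a glue
  copula, which has no offset-map image);
* **apposition** (two NPs separated by a comma, the second starting with
  a determiner or number, not conjuncts): referent-only variant and
  appositive-substituted variant;
* **parenthesized elements**: bracket-removed variant and a variant with
  the parenthesized content standing in for the preceding noun phrase.

Variants are produced by *tree surgery* on the input parse, never by
re-parsing generated text: this keeps all tests parser-free and avoids
compounding parser error, which dominates failure analyses of systems of
this kind. Expansion is recursive (nested constructs are simplified in
all combinations, intermediate variants included, deduplicated by surface
text) and capped at `max_variants` per sentence. The default cap is 128:
a realistic sentence with two parentheticals, a relative clause, two verb
coordinations and a noun-phrase coordination — the package's own worked
example — generates on the order of 70 variants before the buried clause
surfaces, so a 64-variant cap silently truncates exactly the cases
simplification exists for. Extraction is monotone in the variant set
(variants only add matches), so the cap trades recall, never precision.

Attachment ambiguities ("NP1 of NP2 + relative clause", "NP1 and NP2 PP",
"Adj NP1 and NP2") are not resolved; one variant per reading is emitted
and the extractor's semantic type checks select among the readings. Where
types do not discriminate, all surviving readings are proposed.

# Referential relation linking

A captured argument phrase is often not itself an informative named
entity ("the earliest genes", "a membrane glycoprotein", "the protein").
Referential links connect such phrases to the entities that interpret
them:

* part–whole: noun phrases headed by part keywords (locus, promoter,
  domain, residue, site, ...) containing a GGP mention, and
  "NP contains NP" predications;
* member–collection: "including", "such as", "e.g." lists and
  "one/some of NP" partitives;
* hyponymy: "acts as", "is identified as", copular "X is a Y" with one
  named side, and appositives;
* relative-pronoun coreference (the only built-in coreference: general
  anaphora is a separate task, and external resolver output can be merged
  through `register_external_coref()`).

Resolution is a breadth-first search over the document link graph from
the uninformative argument, substituting collection→member,
hypernym→hyponym, apposition in either direction, part→whole and
pronoun→referent, with a visited set over spans so cycles terminate. A
phrase counts as *informative* exactly when it overlaps a pre-annotated
mention; head-noun types (protein, rna, class_noun, ...) gate the slot
type checks and link detection but do not make a phrase informative —
"a membrane glycoprotein" is typed protein yet still resolves through its
apposition to CD14. Every reachable informative mention that satisfies
the slot constraint yields one rewritten pair; if nothing is reachable
the original pair is kept (resolution never discards a pair), though an
event can only be serialized to standoff format when its arguments carry
entity ids, so unresolved placeholders never surface as output events.

Homonymous triggers ("express" for gene expression vs transcription vs
surface localization) are disambiguated at extraction time by type checks
and *lexical guards* (`guard: NP1 ~ mRNA`): a guarded reading is active
at a trigger occurrence only when a pair matched on the guarded slot with
the guard word inside the argument phrase; an active guarded reading
suppresses the same root's unguarded readings at that occurrence.

# Evaluation

Predictions are scored with the approximate span-matching rule of the
community shared tasks: a predicted span is correct if it is entirely
contained in the gold span extended by one token to the left and one to
the right, token boundaries being taken from the supplied parses (the
rule is token-based but the tokenizer is not part of the metric; patrex
uses the document's token layout). Events match when relation, trigger
and role-wise arguments all match under that rule; a gold event whose
argument belongs to an n-member equivalence class is counted n times.
Matching is greedy first-fit in document order, which cannot change
precision or recall on one-to-one gold sets. Nested (regulation-type)
events are outside the package's scope, so the recursive decomposition of
the metric bottoms out at entity spans.

# The synthetic corpus generator

`generate_fixtures()` defines the study conditions for all end-to-end
claims. Each sentence realizes one of the 26 templates with synthetic
entity names (PROT1, PROT2, ...) chosen to miss every typing lexicon, and
is built jointly as text plus gold constituency tree plus gold standoff
annotation, so gold events are known by construction and no parser is
involved. A complication operator is then applied with probability 0.7
(the default mirrors the observation that most corpus sentences are
complex): theme coordination, relative-clause wrapping, apposition,
parenthetical wrapping, member-collection and hyponymy constructions.
Operators are position-aware by design: wrappers that can hide an *agent*
while the theme survives are not applied (a theme is mandatory for an
event, so theme-hiding constructions fail closed, while agent-hiding ones
would emit partial events and make the ablation comparison measure the
gold design rather than the system). Coordination and member-collection
operators apply to directional relations only, because a non-directional
trigger folds all its themes into a single event and a coordinated theme
would change the gold event structure itself.

The default run uses 200 sentences — large enough that every template and
operator appears many times, small enough that the whole suite runs in a
few minutes on one core. On this corpus the full pipeline reaches
precision and recall 1.0 against the generated gold; disabling
simplification or linking lowers recall (by roughly 25–30 and 10 points
respectively) at unchanged precision, reproducing on synthetic data the
qualitative result that simplification and referential linking buy recall
without costing precision. What these tests do *not* show: robustness to
parser error (all trees are gold), real lexical variety (triggers and
sentence frames are drawn from fixed inventories), discourse-level
ellipsis across sentences, or the absolute performance numbers of any
benchmark corpus — those depend on corpora that are deliberately not
bundled.

# Numerical and degenerate-input conventions

All spans are 0-based half-open character intervals; standoff I/O
performs no coordinate conversion. Trigger matching is case-insensitive;
hyphenated compounds ("DNA-binding") match token-internally and take the
left part of the token as the argument span. Duplicate events are folded
in original-text coordinates, so a relation found in several variants or
by several templates counts once. An empty precision or recall
denominator yields 0 by convention. Sentences whose parse fails to read
are skipped with a warning. Two agents on one directional trigger
occurrence produce alternative events with a warning; a trigger
occurrence with no theme produces no event.
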