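# patrex — trigger-driven pattern-based biomedical relation extraction

patrex extracts biomedical events (Phosphorylation, Gene_expression,
Transcription, Protein_catabolism, Localization, Binding) from text with
pre-annotated gene/gene-product mentions. It is aimed at text-mining
practitioners who need a relation extraction system for a *new* relation
without an annotated training corpus: the only task-specific input is a
short **trigger specification** per trigger verb root — its relation,
subcategorization frame, per-argument semantic type constraints, role
assignments and directionality.

From that specification the package:

1. **derives all surface trigger forms** (inflections, process
   nominalizations, adjectival conversions, prefixed variants) by English
   inflection rules plus an exception lexicon — `phosphorylate` →
   *phosphorylates, phosphorylated, phosphorylation, hyperphosphorylation,
   ...*;
2. **instantiates a fixed inventory of 26 pattern templates** (7 verbal,
   9 nominal, 4 adjectival, 6 null-argument) into lexico-syntactic
   patterns, selected by the trigger's frame — e.g. for a transitive
   directional trigger: `NP0 V_tr`, `V_tr NP1`, `NP1 be V_tr:ppart`,
   `N_tr of NP1`, `NP1's N_tr`, `Adj_tr NP1`, `via N_tr`, ...;
3. **matches them over Penn Treebank constituency parses** with a small
   tgrep-style tree-pattern language, choosing the last main verb of each
   consecutive verb group as its head (so "is known to **bind**" matches a
   `bind` pattern) and skipping adverbial and adjective-nominal adjuncts;
4. **simplifies complex sentences** by tree surgery — splitting
   coordinations, detaching relative clauses, substituting appositives and
   parenthesized elements, and emitting alternative attachment readings —
   each variant carrying an offset map back to original coordinates;
5. **links referential relations** (part-whole, member-collection,
   hyponymy, apposition, relative-pronoun coreference; external anaphora
   resolvers can be plugged in) and recursively rewrites arguments that
   are not informative named entities;
6. **reads and writes BioNLP-ST standoff** (`.txt`/`.a1`/`.a2`) and scores
   predictions with the approximate recursive matching metric (a span is
   correct if contained in the gold span extended by one token on each
   side; equivalence classes count an event once per member).

A synthetic document generator (`generate_fixtures()`) builds text, gold
parses, entity annotations and gold events covering every template,
construct and link type, so the whole pipeline is testable without any
corpus download.

## Worked example

```r
library(patrex)

specs <- parse_trigger_spec("
trigger: phosphorylate
relation: Phosphorylation
frame: NP0/NP1
type: NP0 = GGP
type: NP1 = GGP|protein_part
role: NP0 = agent
role: NP1 = theme
direction: directional
affixes: -ion")

patterns <- compile_specs(specs)   # 60 lexico-syntactic patterns

sent  <- "JNK , a stress-activated kinase , phosphorylates NFAT4 and NFATx ."
parse <- "(S (NP (NP (NNP JNK)) (, ,) (NP (DT a) (JJ stress-activated) (NN kinase)) (, ,)) (VP (VBZ phosphorylates) (NP (NP (NNP NFAT4)) (CC and) (NP (NNP NFATx)))) (. .))"
doc <- read_document(sent, parse,
                     a1 = c("T1\tProtein 0 3\tJNK",
                            "T2\tProtein 49 54\tNFAT4",
                            "T3\tProtein 59 64\tNFATx"))

events <- extract_document(doc, patterns)
for (e in events) print(e)
#> <event> Phosphorylation(phosphorylates@[34,48) theme={NFATx} agent={JNK})
#> <event> Phosphorylation(phosphorylates@[34,48) theme={NFAT4} agent={JNK})

cat(write_a2(events, doc$text, doc$mentions), sep = "\n")
#> T4	Phosphorylation 34 48	phosphorylates
#> E1	Phosphorylation:T4 Theme:T3 Cause:T1
#> E2	Phosphorylation:T4 Theme:T2 Cause:T1
```

The apposition is stripped so the subject head resolves to the annotated
`JNK` mention, the coordinated object is split so each conjunct becomes
the theme of its own event, and all spans are reported in the original
sentence's coordinates. Turning simplification off
(`extract_config(simplify = FALSE)`) recovers only the NFATx reading —
this is precisely the recall that simplification buys.

A command-line front end wraps the same functions:

```sh
exec/patrex make-fixtures --seed 1 --n 50 --out-dir fx
exec/patrex extract --specs fx/triggers.spec --text fx/doc.txt \
    --parses fx/doc.parses --offsets fx/doc.offsets --a1 fx/doc.a1 \
    --out pred.a2 [--no-simplify] [--no-linking]
exec/patrex evaluate --pred-dir preds --gold-dir fx
```

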