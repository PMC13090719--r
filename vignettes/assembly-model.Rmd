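---
title: "The ezlink assembly model: type IIS digestion, genetic purification, and iterative fusion-protein builds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ezlink assembly model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezlink)
```

## The problem

Golden Gate / MoClo frameworks assemble transcriptional units from parts with
fixed 4-bp positioning tags, which works well for regulatory elements but
poorly for fusion proteins, where any domain or linker must be appendable at
either end of a growing coding sequence, repeatedly, and in frame. Iterative
pairwise assembly frameworks (iFLinkC and its genetically purified EZ
variant) solve this by recombining exactly two plasmids per cycle — a
destination plasmid pZ carrying the growing open reading frame and a donor
(pD for domains, pL for linkers) carrying the next part — through type IIS
digestion and ligation, with the input DNA removed *genetically*: the product
must carry the resistance marker delivered by the donor (which the old pZ
lacks), must not carry the ccdB counterselection toxin (which the donor
backbone does), and linear DNA is eliminated by T5 exonuclease. The output
plasmid is regenerated into a valid input for the next cycle, so constructs
of arbitrary size grow part by part with a single amino-acid scar per
junction.

`ezlink` is an in silico realization of that framework: a base-accurate
simulator of type IIS digestion and sticky-end ligation, an exhaustive
enumerator of circular ligation products that serves as a brute-force oracle,
reference pZ/donor architectures satisfying the main-text constraints of the
framework, a build planner, and a BsmBI Golden Gate layer compiling
translation units into poly-cistronic constructs. Wet-lab observables
(transformation efficiencies, fluorescence, growth) are outside its scope;
the simulator predicts sequences, products and their uniqueness.

## Enzyme geometry

Type IIS enzymes cut at a fixed offset outside their recognition site. The
registry (a shipped, editable plain-text table,
`inst/extdata/enzymes.tsv`) records recognition and the top/bottom scissile
offsets downstream of the recognition 3' end:

| enzyme | recognition | cut (top/bottom) | overhang |
|--------|-------------|------------------|----------|
| BtsI   | GCAGTG      | 2/0              | 2 nt, 3' |
| BsrDI  | GCAATG      | 2/0              | 2 nt, 3' |
| SapI (= BspQI) | GCTCTTC | 1/4          | 3 nt, 5' |
| BsaI   | GGTCTC      | 1/5              | 4 nt, 5' |
| BbsI   | GAAGAC      | 2/6              | 4 nt, 5' |
| BsmBI  | CGTCTC      | 1/5              | 4 nt, 5' |

`cut_bottom > cut_top` leaves a 5' overhang, `<` a 3' overhang. Two sticky
ends ligate iff they have the same polarity, the same length, and
reverse-complementary overhangs. Blunt ligation is deliberately excluded:
every junction in this chemistry is sticky, and modelling blunt joins would
only create artifact products the protocol suppresses enzymatically.

```{r geometry}
get_enzyme("SapI")
get_enzyme("BtsI")
```

## The elementary cycle and its schedule

A cycle digests pZ with {backbone~pZ~, junction} and the donor with
{backbone~donor~, junction}, pools the fragments, and keeps every circular
ligation product that carries the donor-delivered marker and no ccdB. The
reference architecture implements a **period-2 schedule**:

* odd cycles: junction SapI, pZ backbone BsaI, donor backbone BbsI;
* even cycles: junction BtsI, pZ backbone BbsI, donor backbone BsaI.

The backbone digests are separate, heat-inactivated pre-digests; only the
junction enzyme is active together with the ligase. That constraint forces
two design consequences that the package adopts as its own choices where the
framework's published description leaves them open:

1. **Junction enzymes alternate.** The donor must deliver the *next* cycle's
   junction site downstream of its part. If that site answered to the
   currently active junction enzyme it would be cut in the same pot and the
   keeper destroyed; delivering the other junction enzyme's site keeps it
   inert until the next cycle. This also honours the framework's description
   of digesting with "combinations" of the two junction and two backbone
   enzymes.
2. **The backbone site regenerates across the ligation junction.** All
   backbone cuts expose one constant 4-nt fusion overhang (default `CGCT`).
   On the donor, the backbone recognition sits on the *keeper* side of its
   cut, pointing at the overhang; after ligation with the pZ keeper the
   recognition-spacer-overhang arrangement is reconstituted intact, giving
   the product exactly one backbone site of the *other* backbone enzyme —
   precisely what the next cycle requires. Recognition sites whose job is
   done (the pZ backbone site, both junction recognitions) sit on discard
   fragments and vanish from the product.

## Scars and reading frame

Every junction inserts one glycine (GGT) between consecutive parts:

* SapI junctions use `GGT` itself as the 3-nt fusion overhang;
* BtsI junctions use a designed `GG` 2-nt overhang completed by a fixed `T`
  contributed as the first base of the incoming donor cassette.

The very first junction instead uses the ORF's `ATG` start codon as the
overhang, so a build of *k* parts has exactly *k − 1* scars and translates as
`M · P1 · G · P2 · G · … · Pk`. `verify_orf()` checks that the final ORF is a
whole number of codons and decomposes exactly into this interleaving,
reporting the first out-of-frame junction otherwise.

## The ligation oracle

`enumerate_circular()` explores every circular product formable from a
fragment pool: all subsets up to `max_fragments`, all orders, both
orientations, self-circularisation included, deduplicated by canonical form
(the lexicographically smallest rotation over both strands, computed with
Booth's least-rotation algorithm — a plasmid has no distinguished origin or
strand). Each fragment is used at most once per product; tandem-insert
artifacts can be explored by listing a fragment twice. Enumeration order is
deterministic (pool order, `as_is` before `flipped`) and a frontier guard
(default 10^6 partial chains) bounds pathological pools.

Every designed product in the package — each cycle output, each Golden Gate
compilation — is asserted (in tests) to be an element of this exhaustive
enumeration, and the unique selection-passing one: the in silico analogue of
the framework's observed zero-background stringency. The default
`max_fragments = 2` for elementary cycles mirrors the two-keeper design;
raising it explores three-fragment artifacts, which the selection rules also
eliminate for the reference fixtures.

The no-ligase control disables all joins. Because digestion is modelled as
complete, the only conceivable circular survivors are traces of undigested
input plasmid; both inputs fail selection in a valid design (pZ lacks the
expected marker, the donor carries ccdB), so the control yields zero — and a
donor lacking ccdB, or a pZ already carrying the expected marker, is
immediately flagged as a nonzero count.

## Domestication and boundary hygiene

Parts must not contain recognition sites for the assembly enzymes outside the
designed cassettes. `domesticate()` removes internal sites by synonymous
substitution: a greedy left-to-right scan takes the leftmost occurrence
(either strand), tries the overlapping codons left to right, and applies the
lexicographically smallest synonymous replacement that destroys the
occurrence without increasing the total number of occurrences (one codon swap
can convert one enzyme's site into another's — e.g. His-Cys `CATTGC`/`CACTGC`
— so acceptance requires the global count to strictly decrease). A site that
no synonymous change can destroy is reported as an error.

Sites can also arise *across* the boundaries between sequence blocks when
molecules are concatenated. Two deterministic repair layers keep reference
molecules clean for any seed:

* `ez_config()` assembles every part-free boundary context of the reference
  architectures (plasmid shells with a fixed benign stand-in part) and edits
  single bases inside the adjacent random blocks until no recognition pattern
  crosses any boundary;
* `plan_build()` repairs part-adjacent boundaries by synonymous codon edits,
  propagated to every identical copy of a part so that repeated parts stay
  sequence-identical (tandem copy counting stays exact).

## The synthetic generator

All fixtures are generated, seeded and bit-reproducible: origins, promoter,
RBS and the marker/ccdB modules are random site-free DNA blocks of realistic
sizes (150/60/21/120/90 nt); their *function* is carried by feature
annotation, not sequence realism — the simulator selects on annotated
markers and toxin features, exactly as the genetic purification acts on gene
function, so placeholder sequences lose no generality. Fluorescent-protein
stand-ins are random domesticated CDSs of 236 residues (the FP size class)
with GC fraction in [0.35, 0.65]; real CDSs can be supplied via FASTA
instead. What the generator does *not* emulate: codon-usage bias, repeat-
induced replication instability, expression levels, or any cellular
phenotype — passing tests demonstrate the sequence-level correctness of the
assembly logic, not biological performance of the constructs.

The shipped study conditions are the framework's demonstration builds: a
nine-cycle, five-domain / four-linker monochromatic fusion (one FP stand-in
alternating with a (GGS)~3~ linker; (TP)~4~T is the other built-in linker
chemistry) and a four-TU poly-cistronic compilation on a ccdB acceptor with
validated 4-nt fusion sites (default set `AATG, GCTT, CGAA, TCCG, ACTA`,
screened for duplicates, palindromes and mutual reverse complements).

## Numerical and design choices

* Coordinates are 0-based half-open throughout; circular indices reduce
  modulo length. Circular scissile coordinates of origin-spanning sites are
  kept unreduced so a cut's top/bottom pair remains one coherent interval.
* Fragments store the full region between outermost scissile positions plus
  explicit sticky ends; the physical top strand and the footprint (which sums
  exactly to the parent length over a digest) derive from it.
* Two cuts with overlapping single-stranded scissile regions are an error
  (such designs are invalid), whereas a recognition site too close to a
  linear end to be cleaved is skipped with a warning (matching physical
  behaviour).
* Complete digestion, no kinetics, no partial products; heat inactivation
  appears only through which enzymes are active in which stage.
* T5 exonuclease is modelled as "only circular species are viable"; ccdB as a
  forbidden feature flag (donor propagation in permissive hosts is an
  assumption outside the sequence model); colony counts are not modelled —
  results are product *classes*.
* All randomness flows through explicit integer seeds (sub-seeds stay within
  32-bit range); identical inputs give byte-identical outputs, including the
  GenBank fixtures (the writer emits no timestamps).
* Problem sizes used by the tests and the acceptance script — ~350 bp to
  ~4 kb plasmids, nine-cycle builds, five-molecule Golden Gate pools — were
  chosen as the smallest sizes that exercise every architectural constraint
  (wrap-around digestion, marker alternation, regeneration depth, four-way
  ordering); the full suite runs in well under a minute.

## Known limitations

* BspQI is treated strictly as a SapI isoschizomer; methylation sensitivity
  and star activity are not modelled (base identity only).
* Overhang compatibility is exact-match; there is no thermodynamic scoring of
  near-matched overhangs, because the framework's overhang sets are designed
  orthogonal.
* The reference pZ/pD/pL maps satisfy every constraint stated for the
  framework's plasmids but are not claimed sequence-identical to any
  particular laboratory stock; an optional His-tag-style ORF prefix is not
  modelled (the start module is a bare ATG).
* The Golden Gate layer is the only second-layer chemistry; homology-based
  (Gibson-style) compilation is out of scope.
* `rbs`/`stop`/`adaptor` roles participate as payloads of the adaptor and TU
  builders; the reading-frame planner itself accepts domain and linker parts.
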