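# ezlink

In silico type IIS DNA assembly for iterative fusion-protein cloning.

`ezlink` simulates, at single-base resolution, the iterative pairwise
assembly of fusion-protein open reading frames in the style of genetically
purified iFLinkC (iFLinkC-EZ): a destination plasmid pZ carrying the growing
ORF is recombined with a donor plasmid (pD for a protein domain, pL for a
linker) through type IIS restriction digestion and sticky-end ligation, and
the product is purified *genetically* — it must carry the resistance marker
delivered by the donor, must not carry the donor's ccdB counterselection
toxin, and linear DNA is removed (T5 exonuclease). Each cycle regenerates a
valid input for the next, appending one part with a single amino-acid scar
per junction. A BsmBI Golden Gate layer then compiles finished translation
units into poly-cistronic expression constructs on a ccdB-dropout acceptor.

The package is for synthetic biologists and tool builders who want to
design, validate or debug such builds before (or instead of) touching a
pipette: it predicts every fragment, every circular ligation product, and
whether the genetic selection leaves exactly one.

## What it computes

* **Digestion** — a registry of type IIS enzymes with REBASE-style cut
  geometry (BtsI `GCAGTG(2/0)` → 2-nt 3′ overhangs, SapI/BspQI
  `GCTCTTC(1/4)` → 3-nt 5′, BsaI `GGTCTC(1/5)`, BbsI `GAAGAC(2/6)`, BsmBI
  `CGTCTC(1/5)` → 4-nt 5′), site finding on both strands of circular or
  linear molecules, and analytical ("virtual gel") digests.
* **Ligation** — overhang-directed joining (same polarity, same length,
  reverse-complement overhangs) and *exhaustive enumeration* of circular
  ligation products up to rotation and strand flip: the brute-force oracle
  against which every designed assembly is checked.
* **The elementary cycle** — reference pZ/donor architectures, digestion +
  ligation + selection (marker switch, no ccdB, circular-only), no-ligase
  controls, and regeneration over arbitrarily many cycles under a period-2
  schedule (junctions SapI/BtsI, backbones BsaI/BbsI, markers resA/resB).
* **Planning** — `plan_build()` turns an ordered part list into one cycle per
  part, predicts all intermediate digest sizes and the final ORF statically,
  and `simulate_build()` must reproduce them exactly; `verify_orf()` checks
  frame and the one-Gly-scar-per-junction invariant.
* **Golden Gate** — adaptor modules with validated 4-nt fusion sites,
  TU plasmid construction, and one-pot BsmBI compilation with order
  verification.
* **Synthesis** — seeded, bit-reproducible generation of domesticated CDSs
  (synonymous removal of internal recognition sites), linkers ((GGS)n,
  (TP)nT), and complete plasmid fixture sets; GenBank/FASTA I/O.

## Worked example

Build FP–(GGS)3–FP, a two-domain fusion with a flexible linker, from
synthetic parts:

```r
library(ezlink)
cfg  <- ez_config(1)                      # seeded blocks + enzyme schedule
dom  <- fp_standin(11, id = "FP1")        # 236-residue FP-sized CDS
lnk  <- linker_cds("GGS", 3)              # (GGS)3, protein "GGSGGSGGS"
plan <- plan_build(list(dom, lnk, dom), cfg)
plan
#> <build_plan> 3 cycle(s): FP1(resB) -> GGSx3(resA) -> FP1(resB)

res <- simulate_build(plan, cfg)
res$final_plasmid
#> <dna_molecule> pZ+pD_FP1: 1802 bp, circular, 7 feature(s)
res$scar_report
#> <scar_report> 2 junction(s), 1 scar residue(s) each
#>   junction protein_position scar_residue junction_enzyme
#> 1        1              238            G            BtsI
#> 2        2              248            G            SapI
```

Three cycles ran (markers alternating resB/resA/resB), each with a unique
surviving circular product; the final 1802-bp plasmid's ORF translates as
M · FP1 · G · GGSGGSGGS · G · FP1 — one glycine scar at each of the two
junctions (positions 238 and 248), none before the first part (its fusion
reuses the ATG start codon as the overhang). A QC digest of the product with
the *next* cycle's enzymes shows the ORF-bearing keeper band and the small
marker band:

```r
analytical_digest(res$final_plasmid, c("BtsI", "BbsI"))
#>    fragment_id size_bp left_polarity left_overhang right_polarity right_overhang uncut
#> 1 pZ+pD_FP1.f1    1668    five_prime          CGCT    three_prime             GG FALSE
#> 2 pZ+pD_FP1.f2     134   three_prime            CC     five_prime           AGCG FALSE
```

A command-line shim over the same functions ships in `inst/cli/ezlink`
(subcommands `digest`, `check`, `cycle`, `plan`, `build`, `gg`,
`domesticate`, `parts`).

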