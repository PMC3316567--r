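---
title: "Reconstructing the evolution of vertebrate selenoproteomes with selevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the evolution of vertebrate selenoproteomes with selevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selevo)
```

## The scientific problem

Selenoproteins carry selenocysteine (Sec), the 21st amino acid, encoded by
UGA — normally a stop codon — whenever a SECIS stem-loop element is present
in the mRNA's 3'-UTR.  The set of selenoprotein genes in a genome (the
selenoproteome) is evolutionarily labile: new members arise by gene
duplication, members are lost outright, and the Sec UGA can mutate into a
cysteine codon in a single step, after which the gene leaves the
selenoproteome while remaining a functional protein.  Conversions in the
opposite direction (Cys to Sec) are not observed in vertebrates, which
makes the residue state a naturally irreversible character.

`selevo` implements the inference machinery for this kind of survey:

* **phyletic event reconstruction** — gene births, losses and Sec-to-Cys
  conversions mapped onto a rooted species tree from a family-by-taxon
  state matrix;
* **SECIS detection** — a structural grammar matcher for the SECIS
  stem-loop;
* **gene geometry** — UTR lengths, UGA-to-SECIS spacing, stop-codon
  readthrough, pseudogene lesion calls;
* **Ka/Ks** — Nei–Gojobori (1986) with Jukes–Cantor correction, the
  classic statistic for deciding whether an apparently dead gene still
  evolves under constraint;
* **model-selection phylogenetics** — BioNJ, likelihood under seven
  empirical amino-acid models, AIC ranking, NNI search, aLRT branch
  support;
* **simulators** that generate every kind of input the analysis functions
  consume, so the whole pipeline is testable without any database access.

## The packaged fixture

The package ships a 24-taxon rooted species tree (named internal nodes:
`Vertebrata`, `Euteleostomi`, `Tetrapoda`, `Amniota`, `Mammalia`, `Theria`,
`Placentalia`, `Percomorpha`, ...) and a phyletic state matrix over 48 gene
families: 45 selenoprotein subfamilies plus three cysteine-only duplicates
(GPx5, GPx4b2, Rdx12) that were born from selenoprotein parents and
converted at birth.  Each cell is one of

* `sec` — the gene is present with a Sec UGA;
* `cys` — a Cys codon replaces the Sec codon;
* `other` — another residue replaces it (the pufferfish SelW2c arginine
  form is the one instance);
* `absent` — the gene is demonstrably not there;
* `missing` — no usable evidence.  `missing` never costs anything against
  any reconstructed state and never triggers a loss, mirroring the survey
  convention that losses are trusted only when corroborated.

Transcription choices that the source tables leave open are taken once,
here: group-level presences become `sec` at every member tip; blanks not
explained by a depicted loss or conversion become `missing` (e.g. SelPb
and SelU1 in frog); the elephant shark is encoded `sec` for all 28
ancestral families, which is what places their origin at the vertebrate
root.  The three Dio3 Sec-to-Cys conversions are placed on the guinea pig,
kangaroo rat and cow terminal branches: the narrative states that Dio3
converted in mammalian lineages without enumerating them, and the event
totals (12 conversions to Cys overall, 8 within mammals, with every other
conversion fixed by the text) force exactly three independent mammalian
Dio3 branches.  One counting convention matters: the "12 conversions"
statistic counts conversions *to cysteine*; the SelW2c Sec-to-arginine
replacement is a conversion event in the `EventSet` (with
`to_state = "other"`) but is tallied separately.

```{r fixture}
fx <- load_paper_fixture()
fx
fixture_census(fx)
```

## Event reconstruction: Dollo presence, then Sankoff residues

Reconstruction is two-phase, because gene presence and residue identity
are different characters with different dynamics.

**Birth and loss (Dollo).**  Each family originates exactly once, on the
branch above the most recent common ancestor of all tips where it is
observed (`infer_birth_branch()`).  Losses are the maximal branches inside
the birth clade whose entire descendant tip set is `absent`/`missing` with
at least one `absent` (`dollo_losses()`); this is the minimal loss set
under single origin, which the tests verify by brute force over all
loss-branch subsets on small trees.

**Residue states (Sankoff).**  Within the birth clade, ancestral
`sec`/`cys`/`other` states minimize transition costs by dynamic
programming (`sankoff_states()`).  The default cost matrix charges 1 for
any change except reversion to `sec`, which is infinite — the
irreversibility constraint.  Ties in the downward choice pass resolve
toward `sec`, then toward the parent's state: since reversion is
impossible, any node with a `sec` descendant must be `sec` on the path to
it, and the rootward-`sec` preference matches the convention of mapping
shared conversions back to their common ancestor.  Tips with
`absent`/`missing` states are unconstrained.  The tests verify the DP
against exhaustive enumeration of all labelings on trees of up to six
tips.

`enumerate_events()` combines the two phases into an `EventSet`: one birth
per family (a *duplication* when the metadata names a parent family and
the birth branch is below the root), the Dollo losses, conversions on
every branch where a `sec` parent label meets a `cys`/`other` child label,
plus one conversion-at-birth for duplication-born families whose state at
birth is not `sec` while the parent family is `sec` on the same branch
(GPx5, GPx4b2, Rdx12).

```{r events}
es <- enumerate_events(fx$tree, fx$matrix, fx$meta)
summary(es)
length(ancestral_selenoproteome(es, "Vertebrata"))
length(ancestral_selenoproteome(es, "Mammalia"))
summary(events_in_clade(es, "Mammalia"))[["n_conversions_to_cys"]]
```

## The SECIS grammar

The experimental literature fixes only two hard constraints for the SECIS
element: the core "quartet" with its invariant non-Watson-Crick GA/GA
pairs (AUGA on the 5' side, GA on the 3' side) and two functionally
important unpaired bases in the apical loop, usually AA, with CC forms in
mammalian SelM and SelO.  Everything else in the scanner is an explicit,
tunable geometry (`secis_params()`), matched by complementarity checks
over index positions rather than thermodynamic folding — a deliberate
choice for testability; a folding-based scorer would be an extension
point, not a replacement.

Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| 5' core motif | `ATGA` (DNA) | the quartet's 5' strand; `RTGA` available |
| 3' core motif | `GA` | the invariant 3' strand |
| helix 2 | 9–15 bp, ≤ 2 non-canonical pairs, G·U canonical | a stem long enough to present the loop, short enough to bound the search |
| apical loop | 7–16 nt, unpaired dinucleotide at offset 2 | room for the AA/CC dinucleotide |
| helix 1 | 6 bp flanking the quartet, strictly paired | the quartet sits *inside* the stem; requiring the closing helix below it is what gives the matcher its specificity |

The helix-1 closure deserves a note.  With core motifs and helix 2 alone,
a random 10 kb sequence contains on the order of one accidental match —
far too many for a usable scanner.  Requiring six strictly paired bases
immediately flanking the quartet (structurally, the top of helix 1)
multiplies the background rate by roughly `0.375^6`, bringing the
expected false-positive rate to about 0.01 per 10 kb while leaving real
(generated) elements untouched.  The tests measure both sides of this
trade on simulated data: ≥ 95% recall of planted elements and ≤ 0.1 hits
per 10 kb on dinucleotide-shuffled backgrounds.

The scanner's score — matched helix-2 pairs minus twice the mismatches,
plus a small bonus for an AA/CC apical dinucleotide — is used only to
resolve overlapping candidate placements, never as a detection threshold.

## Gene geometry conventions

All genomic intervals are 0-based and half-open; every distance is
measured on the spliced transcript, so inserting an intron between the
UGA and the SECIS changes nothing (a property test).  `uga_to_secis_distance()`
counts the bases strictly between the UGA codon and the SECIS 5' core
start; published per-family averages depend on the original genome set
and an unstated convention, so they serve as sanity ranges only, never as
test expectations.  Distances under 111 nt are flagged (the
experimentally determined minimum spacing lies between 51 and 111 nt).
`readthrough_extension()` translates from the base after the annotated
stop to the next in-frame TAA/TAG, rendering in-frame UGA as `U` — the
convention needed to express the deiodinase-2 situation, where the
annotated stop is itself a UGA and the extension beyond it is 9 nt in
most mammals and 21 nt in primates.  `classify_sec_site()` treats TGA as
Sec (selenoprotein context); translation elsewhere in the package treats
TGA as stop.

Pseudogene lesion detection aligns a candidate to an intact reference CDS
(global, affine gaps, via Biostrings) and reports frameshifts
(indel length ≢ 0 mod 3), frame-preserving triplet indels, and premature
stops in the candidate's own reading frame — a TGA aligned to the
reference's Sec TGA is not a lesion.  Candidates covering less than half
the reference are rejected as insufficient homology rather than scored.

## Ka/Ks

`nei_gojobori()` implements the 1986 counting method: per-codon
synonymous site fractions from the single-base neighbours (changes to
stop codons excluded from the denominator), multi-position codon
differences averaged over all minimal mutational pathways that avoid stop
codons (re-weighted equally; if every pathway is blocked, all are used),
sites averaged between the two sequences, and Jukes–Cantor correction
with an explicit saturation flag at p ≥ 3/4.  When Ks is zero the ratio
is reported as undefined rather than infinite.  The survey's printed
ratios (1.58 for the primate GPx1 pseudogene, 0.59 for the SelW
pseudogene) cannot be recomputed without the original sequences; they are
used as *recovery scenarios*: codon data simulated at those ω values with
the package's own GY94-style simulator (uniform codon frequencies, no
transition/transversion bias — adequacy, not realism) must yield mean
NG86 estimates within ±0.25 and ±0.15 respectively, and ω = 1 data must
land in [0.85, 1.15], all at 3000 codons over 20 seeds.

## Phylogenetics

The phylogenetic workflow mirrors the survey's procedure: a BioNJ
starting topology (`ape::bionj` behind a validating wrapper;
Poisson-corrected distances), fixed-topology likelihood under seven
empirical amino-acid models (JTT, LG, WAG, Blosum62, MtREV, VT, Dayhoff),
AIC ranking, NNI hill-climbing under the two best models, and aLRT branch
support.  The pruning engine is implemented in the package (phangorn
supplies only the published exchangeability matrices and serves as an
independent cross-check in the tests; brute-force summation over
ancestral states is the primary oracle, agreeing to 1e-9).

Numerical choices: each model uses its published equilibrium frequencies
(no `+F` optimization), so all models share the same parameter count and
AIC ranking reduces to likelihood ranking; rate heterogeneity is off by
default (no gamma categories); gaps and ambiguity codes are fully missing
states; branch lengths are optimized by bracketed one-dimensional search
per branch (tolerance 1e-8 on the length) with up/down message passing
for cheap per-branch evaluations and an exact pruning re-check so the
log-likelihood never decreases; sweeps stop when a full pass gains less
than 1e-6 log units.  aLRT support is the CDF of the
½χ²₀ + ½χ²₁ mixture at twice the log-likelihood gap between the best and
second-best of the three NNI configurations around the branch — 0.5 at a
statistic of zero, 0 when the current topology is not the best
configuration.

## What the simulators do and do not emulate

The genome simulator plants single-exon selenoprotein gene models
(ATG-led CDS with one in-frame TGA, a stop codon, and a
grammar-conformant SECIS in the 3'-UTR) on a uniform-random background;
it does not model genome composition, introns inside CDS, or repeat
structure.  The codon simulator is GY94-style with uniform codon
frequencies; the amino-acid simulator draws i.i.d. sites with no indels.
Every simulator is a pure function of its configuration and seed.
Passing tests on these inputs demonstrate that the *measurement* code is
correct under the stated models — planted-truth recall, estimator
consistency, model recovery — not that real genomes satisfy the models.

Problem sizes used by the test suite were chosen to exercise each method
at desk scale: brute-force oracles on trees of 4–6 tips, likelihood
oracles on 4 taxa x 3 sites, ω recovery at 3000 codons x 20 seeds, SECIS
recall/specificity over 50 simulated 5-kb genomes, and model recovery on
20 replicates of 500-site 6-taxon alignments.

## Known limitations

* The fixture is a transcription of a published survey at the resolution
  of 24 representative tips; branches absent from the tip set cannot
  carry events, and the Dio3 conversion placement is a documented
  decision, not a published coordinate.
* The SECIS matcher is a grammar, not a folding model; it subclassifies
  neither type 1 vs type 2 elements nor free energies.
* Dollo reconstruction is parsimony, not probabilistic; branch lengths
  are ignored for event inference.
* NG86 is a counting method; no ML (Goldman–Yang) dN/dS, windows, or
  significance tests.
* The ML stage targets small alignments (tens of taxa at most); there is
  no SPR/TBR search and no bootstrap.
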