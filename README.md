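# selevo

Inference machinery for studying the composition and evolution of
vertebrate selenoproteomes — the sets of selenocysteine (Sec) containing
protein genes in vertebrate genomes.

Selenoproteins encode Sec with UGA, normally a stop codon, read through
when a SECIS stem-loop is present in the 3'-UTR.  Selenoproteomes evolve
by three kinds of events: gene **births** (mostly duplications), gene
**losses**, and **Sec→Cys conversions** — a single point mutation that
turns the Sec UGA into a cysteine codon and removes the gene from the
selenoproteome while leaving a functional protein.  Conversions back to
Sec are not observed, so the residue state is an irreversible character.

The package provides, as separately usable modules:

* **Phyletic event reconstruction** — Dollo presence reconstruction
  (single origin, minimal losses; `missing` evidence never counts as
  loss) followed by Sankoff parsimony over `{sec, cys, other}` with
  reversion to Sec forbidden (infinite cost).  `enumerate_events()`
  returns a typed event set anchored to branches of a rooted species
  tree; `ancestral_selenoproteome()` reads off the Sec-state family set
  at any node.
* **A packaged fixture** — a 24-taxon vertebrate species tree and a
  48-family phyletic state matrix (45 selenoprotein subfamilies plus the
  Cys-only duplicates GPx5, GPx4b2, Rdx12), shipped as plain newick/TSV
  under `inst/extdata/`.
* **SECIS scanning** — an explicit structural grammar (core AUGA…GA
  quartet closed by a strictly paired helix below, helix 2 with a
  bounded mismatch allowance, apical loop with the unpaired AA/CC
  dinucleotide), matched by index geometry; `scan_secis()`,
  `validate_core()`, `apical_class()`.
* **Gene geometry** — spliced-transcript UTR lengths, UGA-to-SECIS and
  stop-to-SECIS distances, stop-codon readthrough extensions, Sec-site
  codon classification, and pseudogene lesion detection against an
  intact reference CDS.
* **Ka/Ks** — Nei–Gojobori (1986) with pathway averaging that avoids
  stop codons and Jukes–Cantor correction:
  `Ks = −(3/4)·ln(1 − (4/3)·pS)`, likewise `Ka`; `ratio = Ka/Ks`.
* **Model-selection phylogenetics** — BioNJ starting tree, Felsenstein
  pruning likelihood under seven empirical amino-acid models (JTT, LG,
  WAG, Blosum62, MtREV, VT, Dayhoff), AIC ranking (`AIC = 2k − 2·logL`),
  NNI hill-climbing, and aLRT branch support from the ½χ²₀ + ½χ²₁
  mixture.
* **Seeded simulators** for genomes with planted selenoprotein gene
  models, codon evolution at a fixed dN/dS, pseudogenization lesions,
  and amino-acid alignments evolved on a tree.

## Worked example

```r
library(selevo)

fx <- load_paper_fixture()
fixture_census(fx)
#>   n_subfamilies          n_fish       n_mammals    n_all_groups
#>              45              41              28              21

es <- enumerate_events(fx$tree, fx$matrix, fx$meta)
summary(es)
#>             n_families               n_births         n_duplications
#>                     48                     48                     20
#>               n_losses   n_conversions_to_cys n_conversions_to_other
#>                     10                     12                      1
#>    n_conversions_total
#>                     13

length(ancestral_selenoproteome(es, "Vertebrata"))
#> [1] 28
length(ancestral_selenoproteome(es, "Mammalia"))
#> [1] 25
selenoproteome_size(fx$matrix, "zebrafish")
#> [1] 38
```

Reading: the 48 families yield 48 births, of which 20 are duplications;
10 losses; 12 Sec→Cys conversions (8 of them inside the mammalian
subtree), plus the single Sec→Arg replacement (pufferfish SelW2c) tallied
separately.  The reconstructed ancestral vertebrate selenoproteome has 28
members, the ancestral mammalian one 25; zebrafish carries the largest
extant selenoproteome (38), frog the smallest (24).

A simulated end-to-end run of the sequence-level modules:

```r
sim  <- simulate_genome(sim_config(seed = 5, n_genes = 3))
hits <- scan_secis(sim$sequence)                  # finds the 3 planted SECIS
g    <- truth_genes(sim)[[1]]
gene_features(g, sim$sequence)                    # UTRs, UGA-to-SECIS, readthrough

anc  <- paste(sample(setdiff(selevo:::sense_codons(), "TGA"), 3000, TRUE), collapse = "")
des  <- evolve_codons(anc, omega = 0.59, t = 0.3, seed = 1)
nei_gojobori(anc, des)$ratio                      # ~0.6: purifying selection
```

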