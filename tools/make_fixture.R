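# Builds the packaged vertebrate selenoproteome fixture under inst/extdata/:
#   - selevo_tree.nwk         rooted species tree, named internal nodes
#   - selevo_states.tsv       long-format phyletic state matrix (family, taxon, state)
#   - selevo_family_meta.tsv  per-family parent family / subfamily flag / notes
# Run from the package root:  Rscript tools/make_fixture.R

fish   <- c("zebrafish", "medaka", "stickleback", "fugu", "pufferfish")
perco  <- c("medaka", "stickleback", "fugu", "pufferfish")
birds  <- c("chicken", "zebra_finch")
marsup <- c("opossum", "wallaby")
plac   <- c("human", "chimp", "gorilla", "marmoset", "mouse", "rat",
            "squirrel", "guinea_pig", "kangaroo_rat", "rabbit", "dog", "cow")
tetra  <- c("frog", birds, "platypus", marsup, plac)
taxa   <- c("elephant_shark", fish, tetra)

newick <- paste0(
  "(elephant_shark:1,((zebrafish:1,((medaka:1,stickleback:1)Smegmamorpha:1,",
  "(fugu:1,pufferfish:1)Tetraodontidae:1)Percomorpha:1)Clupeocephala:1,",
  "(frog:1,((chicken:1,zebra_finch:1)Aves:1,(platypus:1,((opossum:1,wallaby:1)",
  "Marsupialia:1,((dog:1,cow:1)Laurasiatheria:1,((rabbit:1,(squirrel:1,",
  "guinea_pig:1,kangaroo_rat:1,(mouse:1,rat:1)Murinae:1)Rodentia:1)Glires:1,",
  "(marmoset:1,(gorilla:1,(human:1,chimp:1)Hominini:1)Homininae:1)Primates:1)",
  "Euarchontoglires:1)Placentalia:1)Theria:1)Mammalia:1)Amniota:1)Tetrapoda:1)",
  "Euteleostomi:1)Vertebrata;")

# The 28 families of the ancestral vertebrate selenoproteome (Discussion list).
ancestral <- c("GPx1", "GPx2", "GPx3", "GPx4", "TR1", "TR3", "Dio1", "Dio2",
               "Dio3", "SelH", "SelI", "SelJ", "SelK", "SelL", "SelM", "SelN",
               "SelO", "SelP", "SelPb", "MsrB1", "SelS", "SelT1", "SelU1",
               "SelW1", "SelW2", "Sep15", "Fep15", "SPS2a")

st <- matrix("absent", nrow = 0, ncol = length(taxa))
states <- list()
set_states <- function(fam, default, ...) {
  s <- setNames(rep(default, length(taxa)), taxa)
  ov <- list(...)
  for (k in names(ov)) s[ov[[k]]] <- k
  states[[fam]] <<- s
}

for (f in ancestral) set_states(f, "sec")

# Lineage losses / conversions among the ancestral families.
states[["SelJ"]][tetra]   <- "absent"   # fish-only today, lost on the tetrapod stem
states[["SelL"]][tetra]   <- "absent"
states[["Fep15"]]["frog"] <- "cys"      # Cys homolog in frog; lost before reptiles
states[["Fep15"]][c(birds, "platypus", marsup, plac)] <- "absent"
states[["SelW2"]][c(birds, "platypus", marsup, plac)] <- "absent"
states[["SelPb"]]["frog"] <- "missing"  # Table-1 blank without a depicted event
states[["SelPb"]][plac]   <- "absent"   # lost before the placental split
states[["SPS2a"]][plac]   <- "absent"   # replaced by SPS2b in placentals
states[["SelU1"]]["frog"] <- "missing"
states[["SelU1"]][c(marsup, plac)] <- "cys"   # converted at the therian stem
states[["SelW1"]][perco]  <- "absent"   # lost in Percomorpha
states[["Dio3"]][c("guinea_pig", "kangaroo_rat", "cow")] <- "cys"

# Duplication-born selenoprotein subfamilies (17 Sec subfamilies).
set_states("GPx1b",  "absent", sec = setdiff(fish, "medaka"))  # lost in medaka
set_states("GPx3b",  "absent", sec = fish)
set_states("GPx4b",  "absent", sec = fish)
set_states("Dio3b",  "absent", sec = fish)
set_states("SelT2",  "absent", sec = fish)
set_states("MsrB1b", "absent", sec = fish)
set_states("SelU1c", "absent", sec = fish)
set_states("SelO2",  "absent", sec = "zebrafish")
set_states("SelT1b", "absent", sec = "zebrafish")
set_states("SelW2b", "absent", sec = "zebrafish")
set_states("SelJ2",  "absent", sec = c("medaka", "stickleback"))
set_states("SelU1b", "absent", sec = c("fugu", "pufferfish"), cys = "stickleback")
set_states("SelW2c", "absent", sec = c("medaka", "stickleback", "fugu"),
           other = "pufferfish")                       # Sec -> Arg (CGA)
set_states("TGR",    "absent", sec = tetra)
set_states("SPS2b",  "absent", sec = c(marsup, plac))
set_states("GPx6",   "absent", sec = setdiff(plac, c("marmoset", "mouse", "rat", "rabbit")),
           cys = c("marmoset", "mouse", "rat", "rabbit"))
set_states("SelV",   "absent", sec = setdiff(plac, "gorilla"))  # deleted in gorilla

# Cys-only duplicates (converted at birth; not selenoprotein subfamilies).
set_states("GPx5",   "absent", cys = plac)
set_states("GPx4b2", "absent", cys = "medaka")
set_states("Rdx12",  "absent", cys = tetra)

fam_order <- names(states)
long <- do.call(rbind, lapply(fam_order, function(f)
  data.frame(family = f, taxon = taxa, state = unname(states[[f]]),
             stringsAsFactors = FALSE)))

parent <- c(GPx1b = "GPx1", GPx3b = "GPx3", GPx4b = "GPx4", Dio3b = "Dio3",
            SelT2 = "SelT1", MsrB1b = "MsrB1", SelU1c = "SelU1",
            SelO2 = "SelO", SelT1b = "SelT1", SelW2b = "SelW2",
            SelJ2 = "SelJ", SelU1b = "SelU1", SelW2c = "SelW2",
            TGR = "TR1", SPS2b = "SPS2a", GPx6 = "GPx3", SelV = "SelW1",
            GPx5 = "GPx3", GPx4b2 = "GPx4b", Rdx12 = "SelW2")
notes <- c(Fep15 = "Sec in cartilaginous and bony fish; Cys homolog in frog",
           SelW2c = "Sec replaced by arginine (CGA) in pufferfish",
           GPx5 = "Cys in all placentals; converted at birth",
           GPx4b2 = "Cys copy of GPx4b in medaka; converted at birth",
           Rdx12 = "Cys homolog of SelW2 in all tetrapods; converted at birth",
           SPS2b = "intronless retrogene of SPS2a",
           Dio3b = "intronless, like Dio3")
meta <- data.frame(
  family = fam_order,
  parent_family = ifelse(fam_order %in% names(parent), parent[fam_order], ""),
  selenoprotein_subfamily = !(fam_order %in% c("GPx5", "GPx4b2", "Rdx12")),
  notes = ifelse(fam_order %in% names(notes), notes[fam_order], ""),
  stringsAsFactors = FALSE)

out <- file.path("inst", "extdata")
writeLines(newick, file.path(out, "selevo_tree.nwk"))
write.table(long, file.path(out, "selevo_states.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(meta, file.path(out, "selevo_family_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("families:", length(fam_order), " subfamilies:",
    sum(meta$selenoprotein_subfamily), " cells:", nrow(long), "\n")
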