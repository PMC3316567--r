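(elephant_shark:1,((zebrafish:1,((medaka:1,stickleback:1)Smegmamorpha:1,(fugu:1,pufferfish:1)Tetraodontidae:1)Percomorpha:1)Clupeocephala:1,(frog:1,((chicken:1,zebra_finch:1)Aves:1,(platypus:1,((opossum:1,wallaby:1)Marsupialia:1,((dog:1,cow:1)Laurasiatheria:1,((rabbit:1,(squirrel:1,guinea_pig:1,kangaroo_rat:1,(mouse:1,rat:1)Murinae:1)Rodentia:1)Glires:1,(marmoset:1,(gorilla:1,(human:1,chimp:1)Hominini:1)Homininae:1)Primates:1)Euarchontoglires:1)Placentalia:1)Theria:1)Mammalia:1)Amniota:1)Tetrapoda:1)Euteleostomi:1)Vertebrata;
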