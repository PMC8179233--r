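# Common non-aromatic solvents excluded from the labelled pair dataset.
# One SMILES per line, optional name after whitespace. Editable resource:
# the source publication names no explicit list, so this default collects
# the usual crystallization solvents. Aromatic solvents (benzene, toluene)
# are deliberately absent - they are retained as genuine pi-pi co-formers.
O water
CO methanol
CCO ethanol
CC(C)O isopropanol
CC(C)=O acetone
CC#N acetonitrile
ClCCl dichloromethane
ClC(Cl)Cl chloroform
C1CCOC1 tetrahydrofuran
C1COCCO1 dioxane
CN(C)C=O dimethylformamide
CS(C)=O dimethylsulfoxide
CCOC(C)=O ethyl_acetate
CCOCC diethyl_ether
CCCCCC hexane
CCCCC pentane
C1CCCCC1 cyclohexane
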