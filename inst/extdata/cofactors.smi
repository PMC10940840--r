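# Cofactors and ubiquitous co-substrates excluded from substrate-product
# pairs. One SMILES per line; edit or replace via read_cofactor_list().
# Entries are canonicalized on load, so any valid dialect works.
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O            # ATP
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)OP(=O)(O)O)C(O)C1O                      # ADP
Nc1ncnc2n(cnc12)C1OC(COP(=O)(O)O)C(O)C1O                               # AMP
NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O   # NAD+
NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O    # NADH
NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(OP(=O)(O)O)C2O)C(O)C1O  # NADP+
NC(=O)C1=CN(C=CC1)C1OC(COP(=O)(O)OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc34)C(OP(=O)(O)O)C2O)C(O)C1O   # NADPH
CC(C)(COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc23)C(O)C1OP(=O)(O)O)C(O)C(=O)NCCC(=O)NCCS      # coenzyme A
CC(=O)SCCNC(=O)CCNC(=O)C(O)C(C)(C)COP(=O)(O)OP(=O)(O)OCC1OC(n2cnc3c(N)ncnc23)C(O)C1OP(=O)(O)O # acetyl-CoA
Cc1cc2nc3c(=O)[nH]c(=O)nc-3n(CC(O)C(O)C(O)COP(=O)(O)OP(=O)(O)OCC3OC(n4cnc5c(N)ncnc45)C(O)C3O)c2cc1C  # FAD
Cc1cc2c(cc1C)N(CC(O)C(O)C(O)COP(=O)(O)OP(=O)(O)OCC1OC(n3cnc4c(N)ncnc34)C(O)C1O)c1[nH]c(=O)[nH]c(=O)c1N2  # FADH2
OP(=O)(O)O                                                             # phosphate
OP(=O)(O)OP(=O)(O)O                                                    # diphosphate
O=C=O                                                                  # CO2
O                                                                      # water
O=O                                                                    # O2
[H+]                                                                   # proton
N                                                                      # ammonia
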