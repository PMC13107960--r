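# 100-molecule hand-built fixture set: drug-like molecules and deliberately
# awkward structures used by the annotation-oracle tests. Achiral forms.
CC(=O)Oc1ccccc1C(=O)O
CC(C)Cc1ccc(cc1)C(C)C(=O)O
Cn1cnc2c1c(=O)n(C)c(=O)n2C
CC(=O)Nc1ccc(O)cc1
c1ccc(cc1)C(=O)O
OCC(O)CO
NCCc1ccc(O)c(O)c1
CN1CCC(CC1)c1ccccc1
O=C(O)c1ccccc1O
Clc1ccccc1C(=O)O
CC(N)Cc1ccccc1
COc1ccc(CC(=O)O)cc1
CCOC(=O)c1ccccc1N
NC(=O)c1ccccc1
N#Cc1ccccc1
O=[N+]([O-])c1ccccc1
Oc1ccccc1
Nc1ccccc1
CSc1ccccc1
Sc1ccccc1
FC(F)(F)c1ccccc1
CC(=O)c1ccccc1
O=Cc1ccccc1
OC(=O)CCC(=O)O
NCCCCN
OCCOCCO
C1CCNCC1
C1CCOC1
c1ccsc1
c1ccoc1
c1cc[nH]c1
c1ccncc1
c1ccc2ccccc2c1
c1ccc2[nH]ccc2c1
CC1CCCCC1
CCCCCCCC
CC(C)(C)O
CC(C)=CC
CC#CC
C=CC=C
OC#CCO
ClCCCl
BrCCBr
ICCI
CCS
CCSSCC
CS(=O)(=O)O
NS(=O)(=O)c1ccccc1
OP(=O)(O)OCC
CCOP(=O)(OCC)OCC
NC(=N)NCCC
NC(=O)NCC
CNC(=O)N(C)C
CC=NO
CC(=NO)C
CN=C=O
CCN(CC)CC
c1ccc(cc1)c1ccccc1
Oc1ccc(Cl)cc1
Nc1ccc(F)cc1
COc1ccccc1OC
CC(=O)OCC(=O)O
OCc1ccco1
OCc1cccs1
NCc1ccc[nH]1
CC(O)c1ccccc1
CCC(=O)NC
CC(C)NCC(O)c1ccccc1
CON=C(C)C
CC(=O)CC(=O)C
O=C1CCCCC1
O=C1CCCN1
O=C1OCCC1
N#CCC#N
OC(=O)C=CC(=O)O
CC(Cl)C(=O)O
NCC(=O)O
CC(N)C(=O)O
OC(=O)CN(CC(=O)O)CC(=O)O
CCOC(=O)CC(=O)OCC
CC1CC(=O)NC1
Oc1ccc2ccccc2c1
CC(=O)Nc1ccccc1C
Fc1ccc(F)cc1
Clc1cccc(Cl)c1
Brc1ccccc1O
Ic1ccccc1N
CSCC(N)C(=O)O
OCC1CCCO1
NC1CCCCC1
CC(C)(C)NCC(O)c1ccc(O)c(O)c1
CN(C)CCCN
CCCC=O
CC(C)CC=O
OCC=CC=CCO
CCSC(=O)C
CP(=O)(C)C
CCn1ccc2ccccc21
CC(=O)N1CCCC1
CN1CCN(C)CC1
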