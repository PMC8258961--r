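gene_symbol,accession,syndromes,group
A2ML1,A8K2U0,NSL,
BRAF,P15056,NS;NSML;CFC,
CBL,P22681,NSL;JMML,
HRAS,P01112,CS,RAS
KAT6B,Q8WYB5,NSL,
KRAS,P01116,NS;CFC;JMML,RAS
LZTR1,Q8N653,NS,
MAP3K8,P41279,NSL,
MAP2K1,Q02750,NS;NSML;CFC,MEK1/2
MAP2K2,P36507,CFC,MEK1/2
MRAS,O14807,NS,RRAS
NF1,P21359,NF1;NFNS;JMML,
NRAS,P01111,NS;JMML,RAS
PPP1CB,P62140,NSLSH,
PTPN11,Q06124,NS;NSML;NFNS;JMML,
RAF1,P04049,NS;NSML,
RASA1,P20936,CM-AVM,
RASA2,Q15283,NS,
RIT1,Q92963,NS,
RRAS,P10301,NSL,RRAS
RRAS2,P62070,NS,RRAS
SHOC2,Q9UQ13,NSLSH,
SOS1,Q07889,NS,
SOS2,Q07890,NS,
SPRED1,Q7Z699,LS,
SPRY1,O43609,NSL,
SYNGAP1,Q96PV0,Autism,
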