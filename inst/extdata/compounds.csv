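id,formula,role,mass
CBZ,C7H10N2O2S,ligand,185.2
VO-CBZ,C7H26N2O15S2V,complex,493.3
CTZ,C21H27Cl3N2O3,ligand,461.8
VO-CTZ,C42H52Cl2N4O9V,complex,878.7
LOR,C13H10ClN3O4S2,ligand,371.8
VO-LOR,C26H20Cl2N6O11S5V,complex,906.6
SCZ,C10H9ClN4O2S,ligand,250.1
VO-SCZ,C10H23N4O14S2V,complex,573.8
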