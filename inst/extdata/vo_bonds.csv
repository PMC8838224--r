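id,nu_exp,nu_dft,r_exp,r_dft
VO-CBZ,980,1037,1.607,1.599
VO-CTZ,963,1068,1.616,1.579
VO-LOR,968,1075,1.613,1.576
VO-SCZ,987,1047,1.603,1.596
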