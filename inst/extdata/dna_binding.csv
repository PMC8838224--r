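id,k_b,lambda_free,lambda_bound,chromism
CBZ,8.33e5,261,255,hyperchromic
VO-CBZ,5.00e5,265,256,hyperchromic
CTZ,1.00e6,263,263,hyperchromic
VO-CTZ,1.40e6,265,259,hyperchromic
LOR,8.33e5,395,376,hypochromic
VO-LOR,1.20e6,281,274,hyperchromic
SCZ,1.00e6,265,257,hyperchromic
VO-SCZ,1.25e6,262,256,hyperchromic
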