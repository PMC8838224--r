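id,e_homo_eV,e_lumo_eV,delta_e,chi,eta,sigma1,mu,sigma2,s,omega,dn_max
CBZ,-5.55,-1.00,4.55,3.28,2.28,0.44,-3.28,0.44,1.14,2.36,1.44
VO-CBZ,-7.09,-3.27,3.83,5.18,1.91,0.52,-5.18,0.96,0.96,2.59,2.71
SCZ,-6.75,-2.78,3.97,4.77,1.99,0.50,-4.77,0.99,0.99,2.38,2.40
VO-SCZ,-7.41,-3.64,3.77,5.53,1.89,0.53,-5.53,0.94,0.94,2.76,2.93
LOR,-3.96,-1.99,1.97,2.98,0.98,1.02,-2.98,0.49,0.49,1.49,3.03
VO-LOR,-3.93,-2.74,1.19,3.34,0.59,1.68,-3.34,0.30,0.30,1.67,5.62
CTZ,-6.59,-4.68,1.91,5.64,0.95,1.05,-5.64,0.48,0.48,2.82,5.91
VO-CTZ,-10.26,-8.84,1.42,10.05,1.21,0.83,-10.05,0.61,0.61,5.03,8.31
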