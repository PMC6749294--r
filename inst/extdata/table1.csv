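# Antiparasitic drugs: computed logP scales and RP-TLC descriptors (RP-18F254 plates).
# phi0 columns follow the table ROW labels: the acetone set is the lower one (0.398-0.565);
# the source table's footnote letters for phi0(a)/phi0(m) are swapped relative to the rows.
compound,class,alogps,aclogp,milogp,alogp,mlogp,xlogp2,xlogp3,rmws_a,rmws_m,rmwo_a,rmwo_m,phi0_m,phi0_a
metronidazole,antiparasitic,-0.15,-0.19,-0.47,-0.34,0.44,-0.14,-0.02,0.65,0.91,0.94,1.21,0.564,0.398
ornidazole,antiparasitic,0.37,0.39,0.12,0.36,1.13,0.66,0.60,1.22,1.46,1.42,1.92,0.676,0.565
secnidazole,antiparasitic,0.25,0.21,-0.10,0.04,0.80,0.32,0.22,0.95,1.26,1.21,1.72,0.656,0.503
tinidazole,antiparasitic,-0.41,-0.20,-0.06,0.15,1.00,0.74,-0.36,0.89,1.17,1.11,1.69,0.612,0.463
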