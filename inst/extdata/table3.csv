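# NSAIDs: computed logP scales and RP-TLC descriptors. The acetone-water mobile phase was
# unsuitable for the Oscik extrapolation of these compounds, so rmwo_a is missing throughout.
compound,class,alogps,aclogp,milogp,alogp,mlogp,xlogp2,xlogp3,rmws_a,rmws_m,rmwo_a,rmwo_m,phi0_m,phi0_a
mefenamic acid,nsaid,4.58,4.01,4.77,3.96,3.47,4.16,5.12,2.61,2.49,,3.74,0.865,0.789
indomethacin,nsaid,4.25,3.83,3.99,4.21,3.32,4.18,4.27,2.57,2.19,,4.08,0.790,0.747
nabumetone,nsaid,3.41,3.56,3.40,2.80,3.04,3.06,3.08,3.08,3.12,,2.52,0.903,0.787
phenylbutazone,nsaid,2.81,3.29,4.56,3.95,3.70,3.71,3.16,1.72,1.84,,3.54,0.686,0.715
carprofen,nsaid,4.09,3.79,4.32,4.09,3.18,3.79,4.05,2.56,2.34,,2.77,0.820,0.754
ketoprofen,nsaid,3.29,2.99,3.59,3.34,3.37,3.22,3.12,1.26,1.47,,3.76,0.687,0.640
flurbiprofen,nsaid,3.57,3.46,4.05,3.66,3.89,3.76,4.16,1.87,1.98,,2.26,0.771,0.930
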