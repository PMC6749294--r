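# Antihypertensive (dihydropyridine) drugs: computed logP scales and RP-TLC descriptors.
compound,class,alogps,aclogp,milogp,alogp,mlogp,xlogp2,xlogp3,rmws_a,rmws_m,rmwo_a,rmwo_m,phi0_m,phi0_a
nilvadipine,antihypertensive,2.97,2.63,3.72,2.09,1.72,2.76,2.87,4.07,3.66,6.28,5.57,0.886,0.764
felodipine,antihypertensive,4.36,4.03,4.80,3.55,3.22,4.15,3.86,3.75,4.27,5.57,6.57,0.929,0.775
isradipine,antihypertensive,3.00,3.47,3.81,2.17,1.72,4.12,4.28,3.54,3.13,5.67,5.08,0.837,0.751
lacidipine,antihypertensive,5.18,4.33,5.46,3.82,3.09,4.83,4.55,4.51,5.01,6.63,6.89,0.937,0.793
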