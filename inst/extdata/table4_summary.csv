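# Published mean (+/- sample sd) of the experimental logP values, as printed (2 dp),
# for the compounds with more than one literature value.
compound,logp_mean,logp_sd
metronidazole,0.10,0.44
ornidazole,0.41,0.25
tinidazole,0.18,0.74
felodipine,4.16,0.42
indomethacin,4.18,0.12
ketoprofen,3.13,0.01
flurbiprofen,4.00,0.23
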