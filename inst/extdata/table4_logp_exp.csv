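# Literature experimental n-octanol/water logP values (shake-flask scale), one row per
# reported value. No experimental value exists for nilvadipine, lacidipine or carprofen.
compound,value,source_tag
metronidazole,-0.22,ref34
metronidazole,-0.10,ref35
metronidazole,-0.02,ref36
metronidazole,0.75,ref37
ornidazole,0.23,ref34
ornidazole,0.59,ref38
secnidazole,0.22,ref33
tinidazole,-0.35,ref39
tinidazole,0.70,ref40
felodipine,3.86,ref6
felodipine,4.46,ref41
isradipine,4.28,ref6
mefenamic acid,5.12,ref39
indomethacin,4.10,ref42
indomethacin,4.27,ref36
nabumetone,3.08,ref43
phenylbutazone,3.16,ref36
ketoprofen,3.12,ref36
ketoprofen,3.14,ref44
flurbiprofen,3.84,ref42
flurbiprofen,4.16,ref36
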