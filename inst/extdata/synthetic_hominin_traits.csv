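species,IMI,ECV,BM,SUBS,SOC_SYS
Ardipithecus_ramidus,90,300,50,both,group
Australopithecus_afarensis,85,450,40,terrestrial,group
Homo_ergaster,80,800,60,terrestrial,group
Homo_erectus,75,950,60,terrestrial,group
Homo_floresiensis,87,420,30,terrestrial,group
Homo_neanderthalensis,71,1400,70,terrestrial,group
Homo_sapiens,72,1350,62,terrestrial,group
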