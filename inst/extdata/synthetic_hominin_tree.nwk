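(Pan_troglodytes:7,(Ardipithecus_ramidus:1.1,(Australopithecus_afarensis:1.0,(Homo_ergaster:0.6,(Homo_erectus:1.5,(Homo_floresiensis:0.94,(Homo_neanderthalensis:0.56,Homo_sapiens:0.6):0.4):0.6):0.4):2.0):1.5):1.5);
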