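(Hymenochirus_sp,((tropicalis,(calcaratus,(epitropicalis,mellotropicalis))),((clivii,(borealis,muelleri)),((laevis,(gilli,petersii)),(pygmaeus,parafraseri)))));
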