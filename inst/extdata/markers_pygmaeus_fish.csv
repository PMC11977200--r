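# X. pygmaeus FISH-observed loci (one homeolog copy detected per single-copy
# probe except cept1/gyg2, which hybridise to both chromosomes 2L and 2S).
species,gene,chromosome,arm,rank,region,copy
pygmaeus,cept1,2L,p,1,interstitial,none
pygmaeus,gyg2,2L,p,2,interstitial,none
pygmaeus,gyg2,2S,q,1,pericentromeric,none
pygmaeus,cept1,2S,q,2,pericentromeric,none
pygmaeus,fn1,9_10L,q,1,interstitial,L
pygmaeus,ndufs1,9_10L,q,2,interstitial,L
pygmaeus,nomo3,9_10L,q,4,interstitial,L
pygmaeus,sf3b1,9_10S,q,3,interstitial,S
pygmaeus,bmp7,9_10L,p,1,interstitial,L
pygmaeus,sox9,9_10L,p,2,interstitial,L
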