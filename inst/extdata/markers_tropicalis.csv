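# X. tropicalis (diploid, subgenus Silurana) single-copy gene map: ancestral
# reference positions. Ranks are 1-based from the centromere outward; the
# within-arm orders not resolvable from FISH are a bundled convention.
species,gene,chromosome,arm,rank,region,copy
tropicalis,cept1,2,p,1,interstitial,none
tropicalis,gyg2,2,p,2,interstitial,none
tropicalis,fn1,9,q,1,interstitial,none
tropicalis,ndufs1,9,q,2,interstitial,none
tropicalis,sf3b1,9,q,3,interstitial,none
tropicalis,nomo3,9,p,1,interstitial,none
tropicalis,bmp7,10,p,1,interstitial,none
tropicalis,sox9,10,q,1,interstitial,none
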