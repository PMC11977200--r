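# X. laevis map from genome annotation: cept1 annotated only on 2S, gyg2 only
# on 2L; fusion-associated genes on both 9_10 homeologs. cept1's q-arm
# placement on 2S follows the centromere-coordinate comparison.
species,gene,chromosome,arm,rank,region,copy
laevis,gyg2,2L,p,1,interstitial,L
laevis,cept1,2S,q,1,interstitial,S
laevis,fn1,9_10L,q,1,interstitial,L
laevis,ndufs1,9_10L,q,2,interstitial,L
laevis,sf3b1,9_10L,q,3,interstitial,L
laevis,nomo3,9_10L,q,4,interstitial,L
laevis,bmp7,9_10L,p,1,interstitial,L
laevis,sox9,9_10L,q,5,interstitial,L
laevis,fn1,9_10S,q,1,interstitial,S
laevis,ndufs1,9_10S,q,2,interstitial,S
laevis,sf3b1,9_10S,q,3,interstitial,S
laevis,nomo3,9_10S,q,4,interstitial,S
laevis,bmp7,9_10S,p,1,interstitial,S
laevis,sox9,9_10S,q,5,interstitial,S
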