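# X. mellotropicalis (allotetraploid, subgenus Silurana) map: the sf3b1 gene
# is translocated from chromosome 9b to the pericentromeric region of 2b;
# the a-subgenome retains ancestral positions.
species,gene,chromosome,arm,rank,region,copy
mellotropicalis,cept1,2a,p,1,interstitial,a
mellotropicalis,gyg2,2a,p,2,interstitial,a
mellotropicalis,fn1,9a,q,1,interstitial,a
mellotropicalis,ndufs1,9a,q,2,interstitial,a
mellotropicalis,sf3b1,9a,q,3,interstitial,a
mellotropicalis,nomo3,9a,p,1,interstitial,a
mellotropicalis,bmp7,10a,p,1,interstitial,a
mellotropicalis,sox9,10a,q,1,interstitial,a
mellotropicalis,cept1,2b,p,1,interstitial,b
mellotropicalis,gyg2,2b,p,2,interstitial,b
mellotropicalis,sf3b1,2b,q,1,pericentromeric,b
mellotropicalis,fn1,9b,q,1,interstitial,b
mellotropicalis,ndufs1,9b,q,2,interstitial,b
mellotropicalis,nomo3,9b,p,1,interstitial,b
mellotropicalis,bmp7,10b,p,1,interstitial,b
mellotropicalis,sox9,10b,q,1,interstitial,b
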