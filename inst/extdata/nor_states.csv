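# NOR-bearing chromosome per species. Hymenochirus sp. (outgroup) carries no
# state homologous to Xenopus chromosome labels and is omitted (pruned before
# parsimony, never imputed).
species,nor_chromosome
laevis,3L
gilli,3L
petersii,3L
pygmaeus,6S
parafraseri,6S
clivii,4L
borealis,4L
muelleri,5L
tropicalis,7
calcaratus,7a
epitropicalis,7a
mellotropicalis,7a
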