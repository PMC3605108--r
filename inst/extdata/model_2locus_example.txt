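# epistasim penetrance model
n: 2
mafs: 0.40000000000000002 0.5
order: row-major flat MLG index, locus 1 most significant; genotype 0=AA 1=Aa 2=aa
prevalence: 0.61434
heritability: 0.24253174417933204
values:
0.26600000000000001
0.76400000000000001
0.66400000000000003
0.92800000000000005
0.39800000000000002
0.73299999999999998
0.45600000000000002
0.92700000000000005
0.14699999999999999
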