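# Published per-chromosome marker counts of an LD-pruned (r2 < 0.2)
# autosomal PorcineSNP60 panel used for segment-sharing analysis.
chrom	markers
1	353
2	225
3	196
4	238
5	190
6	181
7	257
8	230
9	202
10	175
11	162
12	132
13	259
14	235
15	238
16	130
17	121
18	97
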