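order_index,probe_id,region,timepoint,mean_beta_pct_male,mean_beta_pct_female,n_male,n_female
1,cg01412654,north_shore,birth,65.8,67.8,188,185
2,cg25929976,north_shore,birth,55.6,58.1,188,185
3,cg18063278,north_shore,birth,59.1,62.1,188,185
4,cg26364899,island,birth,6.3,6.3,188,185
5,cg27095527,island,birth,4.3,4.5,188,185
6,cg06573644,island,birth,6.2,6.4,188,185
7,cg21946299,island,birth,9.0,8.9,188,185
8,cg23514324,island,birth,8.0,8.0,188,185
9,cg04748988,island,birth,2.3,2.3,188,185
10,cg15722404,island,birth,2.8,2.7,188,185
11,cg13518792,island,birth,1.0,1.0,188,185
12,cg09405169,island,birth,1.9,1.8,188,185
13,cg04632671,island,birth,1.0,1.1,188,185
14,cg07556134,island,birth,1.3,1.3,188,185
15,cg18887186,island,birth,9.8,9.9,188,185
16,cg21859053,south_shore,birth,9.4,9.5,188,185
17,cg04908300,south_shore,birth,15.4,15.9,188,185
18,cg16827534,south_shelf,birth,87.8,88.6,188,185
19,cg16197186,five_utr,birth,91.1,91.3,188,185
20,cg18537222,gene_body,birth,51.5,52.1,188,185
21,cg07895576,gene_body,birth,90.1,90.3,188,185
22,cg07676920,gene_body,birth,85.1,85.0,188,185
23,cg10499651,gene_body,birth,79.0,78.8,188,185
1,cg01412654,north_shore,year9,71.5,73.1,113,132
2,cg25929976,north_shore,year9,62.5,65.4,113,132
3,cg18063278,north_shore,year9,68.3,71.1,113,132
4,cg26364899,island,year9,6.0,6.2,113,132
5,cg27095527,island,year9,4.0,4.6,113,132
6,cg06573644,island,year9,5.8,5.8,113,132
7,cg21946299,island,year9,9.1,9.0,113,132
8,cg23514324,island,year9,7.4,7.3,113,132
9,cg04748988,island,year9,2.0,2.0,113,132
10,cg15722404,island,year9,2.8,2.7,113,132
11,cg13518792,island,year9,1.0,1.0,113,132
12,cg09405169,island,year9,2.1,2.1,113,132
13,cg04632671,island,year9,1.4,1.2,113,132
14,cg07556134,island,year9,1.5,1.5,113,132
15,cg18887186,island,year9,12.5,12.5,113,132
16,cg21859053,south_shore,year9,12.3,12.4,113,132
17,cg04908300,south_shore,year9,24.8,25.7,113,132
18,cg16827534,south_shelf,year9,89.7,89.4,113,132
19,cg16197186,five_utr,year9,92.0,91.9,113,132
20,cg18537222,gene_body,year9,57.1,58.4,113,132
21,cg07895576,gene_body,year9,90.7,90.6,113,132
22,cg07676920,gene_body,year9,85.9,85.7,113,132
23,cg10499651,gene_body,year9,77.1,78.2,113,132
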