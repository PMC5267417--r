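probe_id,order_index,region
cg01412654,1,north_shore
cg25929976,2,north_shore
cg18063278,3,north_shore
cg26364899,4,island
cg27095527,5,island
cg06573644,6,island
cg21946299,7,island
cg23514324,8,island
cg04748988,9,island
cg15722404,10,island
cg13518792,11,island
cg09405169,12,island
cg04632671,13,island
cg07556134,14,island
cg18887186,15,island
cg21859053,16,south_shore
cg04908300,17,south_shore
cg16827534,18,south_shelf
cg16197186,19,five_utr
cg18537222,20,gene_body
cg07895576,21,gene_body
cg07676920,22,gene_body
cg10499651,23,gene_body
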