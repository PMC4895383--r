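# Published counts from a large-scale non-homologous (<= 30 % identity)
# lysine-ubiquitylation training compendium: positive / negative window
# counts and the reported sizes of the 12 motif subgroups obtained by
# maximal dependence decomposition of the positive windows.
item	count
positive_windows	5438
negative_windows	12663
subgroup_Ub1	192
subgroup_Ub2	266
subgroup_Ub3	248
subgroup_Ub4	378
subgroup_Ub5	467
subgroup_Ub6	792
subgroup_Ub7	847
subgroup_Ub8	563
subgroup_Ub9	672
subgroup_Ub10	323
subgroup_Ub11	149
subgroup_Ub12	541
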