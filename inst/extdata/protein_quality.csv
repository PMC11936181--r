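protein_id,pdb_id,pct_most_favored
ERK2,8AOJ,90.3
JNK2,7N8T,92.2
p38,6QDZ,90.8
p65,1NFI,79.0
IkBa,AF-P25963-F1-v4,80.9
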