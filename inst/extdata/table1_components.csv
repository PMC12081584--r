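condition,cluster,dG_solv,dG_coul,dG_nonelec,dG_b
0%,Cluster1,231,-73,-52,106
0%,Cluster2,251,-112,-58,81
0%,Cluster3,264,-238,-55,-29
25%,Cluster1,299,-171,-60,68
25%,Cluster2,326,-54,-56,216
25%,Cluster3,239,-115,-60,64
50%,Cluster1,243,-162,-56,25
50%,Cluster2,240,-54,-59,127
50%,Cluster3,271,-122,-59,90
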