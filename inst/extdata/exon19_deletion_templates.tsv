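template_id	cdna_start	cdna_end	genomic_start	genomic_end	length
del2233-2247	2233	2247	55242463	55242477	15
del2235-2246	2235	2246	55242465	55242476	12
del2235-2249	2235	2249	55242465	55242479	15
del2236-2250	2236	2250	55242466	55242480	15
del2236-2256	2236	2256	55242466	55242486	21
del2238-2252	2238	2252	55242468	55242482	15
del2239-2247	2239	2247	55242469	55242477	9
del2239-2256	2239	2256	55242469	55242486	18
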