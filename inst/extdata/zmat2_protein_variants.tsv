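species	length	percent_identity	substitutions
rat	199	99.5	D180>E
guinea_pig	199	99.5	D174>E
rabbit	199	100
cow	199	100
horse	199	100
pig	199	99.5	T7>A
sheep	199	100
goat	199	100
dog	199	100
cat	199	100
elephant	199	100
dolphin	199	100
megabat	199	100
microbat	199	99	R170>K;T176>A
opossum_1	199	99.5	T30>N
opossum_2	199	99	T30>N;V128>M
tasmanian_devil	199	99.5	T30>N
koala	199	99.5	T30>N
human	199	100
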