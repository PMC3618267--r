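ID PU1_short_reconstruction
XX
P0      A       C       G       T
01      94      2       2       2       A
02      2       2       94      2       G
03      48      2       48      2       R
04      2       2       94      2       G
05      2       2       94      2       G
06      94      2       2       2       A
07      94      2       2       2       A
08      2       2       94      2       G
XX
//
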