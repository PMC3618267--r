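ID PU1_long_reconstruction
XX
P0      A       C       G       T
01      48      2       48      2       R
02      94      2       2       2       A
03      94      2       2       2       A
04      94      2       2       2       A
05      2       2       94      2       G
06      48      2       48      2       R
07      2       2       94      2       G
08      2       2       94      2       G
09      94      2       2       2       A
10      94      2       2       2       A
11      2       2       94      2       G
12      2       2       2       94      T
13      2       2       94      2       G
XX
//
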