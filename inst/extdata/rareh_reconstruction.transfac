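ID RAREh_reconstruction
XX
P0      A       C       G       T
01      94      2       2       2       A
02      2       2       94      2       G
03      2       2       94      2       G
04      2       2       2       94      T
05      2       94      2       2       C
06      94      2       2       2       A
XX
//
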