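ID  pbx1_like_synthetic
BF  synthetic construct; TALE-homeodomain-like consensus TGATTGAT
P0      A      C      G      T
01      1      1      1     17      T
02      1      1     16      2      G
03     16      1      1      2      A
04      1      1      1     17      T
05      2      1      2     15      T
06      1      2     16      1      G
07     15      2      1      2      A
08      2      1      2     15      T
XX
//
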