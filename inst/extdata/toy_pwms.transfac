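ID M00751
NA AML1
P0 A C G T
01 1 2 2 15 T
02 0 1 17 2 G
03 2 1 1 16 T
04 1 1 16 2 G
05 1 1 15 3 G
06 2 2 1 15 T
//
ID TOY001
NA ToyBox
P0 A C G T
01 10 0 0 0 A
02 0 10 0 0 C
03 0 10 0 0 C
04 10 0 0 0 A
05 0 10 0 0 C
06 10 0 0 0 A
//
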