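genotype,GY,ASV
H1,4.794568,1.85909
H2,4.712901,1.5837208
H3,5.287778,5.2063954
H4,4.286235,1.0168983
H5,4.52463,1.9948371
H6,4.073333,0.8361593
H7,4.173889,1.0237023
H8,4.349753,1.8637358
H9,4.308518,1.5853866
H10,4.230926,0.745642
H11,4.303364,2.1327229
H12,4.110124,1.6735872
H13,4.465864,1.197241
H14,4.04963,0.5389847
H15,4.287984,0.6993901
H16,4.424321,1.377584
H17,4.399321,0.3045344
H18,4.464198,1.3022106
H19,4.377037,1.3002327
H20,4.077346,0.7095017
T1,4.021049,2.4462294
T2,4.684568,2.2056537
T3,4.370926,0.5914402
T4,3.849568,0.5650185
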