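genotype,CWH,ASV
H1,8.756975,0.2277562
H2,7.79801,0.6156969
H3,8.981728,1.6107813
H4,7.900556,0.1651713
H5,7.339649,0.6140148
H6,7.244609,0.1818535
H7,7.129239,0.485574
H8,7.067195,0.5711775
H9,6.516049,0.3053621
H10,6.740432,1.1629429
H11,7.611432,1.1809348
H12,9.624568,2.4395253
H13,7.401204,0.7551079
H14,6.833395,0.456236
H15,7.279993,0.475011
H16,7.763774,0.3834887
H17,7.337333,0.8336439
H18,7.390317,0.3435281
H19,6.760216,0.5573242
H20,6.733796,0.4081656
T1,5.936111,1.908563
T2,7.517938,0.5359845
T3,8.091738,1.3465013
T4,6.548452,0.1526591
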