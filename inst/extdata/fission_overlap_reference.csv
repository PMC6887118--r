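mito_length_um,summed_patch_length_um
7.17,0.47
6.90,0.69
12.00,1.1
8.15,0.69
16.78,3.69
7.35,0.53
3.94,0.65
10.24,0.75
9.65,0.75
4.10,0.69
7.48,0.75
6.65,0.69
16.78,0.23
5.87,0.69
4.70,0.50
8.30,0.75
6.90,0.80
7.70,0.78
11.30,0.86
4.40,0.56
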