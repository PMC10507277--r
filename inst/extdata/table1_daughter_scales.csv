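name,surface_area_um2,contact_area_um2
D1,10.470,0.000
D2,9.827,0.000
D3,8.692,0.000
D4,8.615,0.000
D5,8.459,0.000
D6,10.490,0.000
D7,11.044,0.017
D8,13.555,0.000
D9,15.002,0.000
D10,16.842,0.020
D11,18.165,0.017
D12,21.033,0.081
D13,21.876,0.069
D14,22.709,0.014
D15,23.345,0.026
D16,24.632,1.355
D17,24.796,1.087
D18,26.362,0.299
D19,26.857,1.972
D20,28.885,1.199
D21,27.313,2.277
D22,27.621,9.542
D23,28.885,28.885
D24,27.477,27.479
D25,28.988,0.050
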