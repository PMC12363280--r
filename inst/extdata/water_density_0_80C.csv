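temperature_c,density_g_ml
0,0.999840
5,0.999964
10,0.999699
15,0.999099
20,0.998203
25,0.997044
30,0.995646
35,0.994029
40,0.992212
45,0.990208
50,0.988030
55,0.985688
60,0.983191
65,0.980546
70,0.977759
75,0.974837
80,0.971785
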