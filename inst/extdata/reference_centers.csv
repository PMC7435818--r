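label,x_R,y_R,x_G,y_G,x_B,y_B,h_R,h_G,h_B,f_R,f_G,f_B
2 min,0.91,0.80,1.16,0.82,0.72,0.40,70,102,72,271,275,380
4 min,0.93,0.88,1.09,0.91,0.76,0.53,95,107,65,254,246,352
6 min,0.68,1.02,0.77,1.03,0.56,0.74,62,66,64,241,232,281
8 min,0.54,1.12,0.58,1.10,0.43,0.95,56,57,56,182,195,221
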