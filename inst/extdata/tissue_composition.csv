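tissue,f_water,f_nl,f_pl,f_protein,ph
adipose,0.18,0.79,0.002,0.049,7.1
bone,0.41,0.074,0.0011,0.100,7.0
brain,0.77,0.051,0.0565,0.048,7.1
gut,0.77,0.0487,0.0163,0.158,7.0
heart,0.76,0.0115,0.0166,0.157,7.1
kidney,0.78,0.0207,0.0162,0.130,7.22
liver,0.75,0.0348,0.0252,0.086,7.23
lung,0.81,0.003,0.009,0.212,6.6
muscle,0.76,0.0238,0.0072,0.064,7.0
skin,0.72,0.0284,0.0111,0.277,7.0
spleen,0.79,0.0201,0.0198,0.097,7.0
rest,0.76,0.04,0.01,0.100,7.0
plasma,0.945,0.0023,0.0013,1.0,7.4
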