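# Species grand means of call excess attenuation (dB) over both substrates
# and all four distances (linear-scale averages reconverted to dB), with the
# reported SD and range.
species,mean_db,sd_db,min_db,max_db
P_perezi,3.64,2.5,-9.87,18.13
L_catesbeianus,1.04,2.6,-11.39,12.41
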