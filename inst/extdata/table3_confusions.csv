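test,cutoff,tn,tp,fn,fp
cnv_z,2,3,15,1,6
cnv_z,2.5,9,13,3,0
cnv_z,3,9,8,8,0
ft_psa,10,7,9,7,2
ft_psa,16,4,11,5,5
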