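t_start_h,t_end_h,mean_mmol_l,sd_mmol_l
1008,1176,42.0,5.0
1176,1344,44.5,5.0
1344,1512,46.0,5.5
1512,1680,45.0,5.0
1680,1848,46.5,5.5
1848,2016,44.0,5.0
2016,2352,31.5,1.5
2352,2688,32.5,1.5
2688,3024,32.0,1.5
3024,3360,31.0,1.5
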