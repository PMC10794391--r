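test,threshold,sen_pct,sen_lower_pct,sen_upper_pct,spe_pct,spe_lower_pct,spe_upper_pct,n_pos,n_neg
testA,1,96.3,89.6,98.7,16.3,9.8,25.9,80,80
testA,2,96.3,89.6,98.7,22.5,14.7,32.8,80,80
testA,3,93.8,86.3,97.3,28.8,20.0,39.5,80,80
testA,4,83.8,74.2,90.3,42.5,32.3,53.4,80,80
testB,1,57.5,46.6,67.7,81.3,71.4,88.3,80,80
testB,2,51.3,40.5,61.9,91.3,83.1,95.7,80,80
testB,3,43.8,33.4,54.7,98.8,93.3,99.8,80,80
testB,4,41.3,31.2,52.2,100.0,95.4,100.0,80,80
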