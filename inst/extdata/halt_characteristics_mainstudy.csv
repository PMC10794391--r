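test,threshold,sen_pct,sen_lower_pct,sen_upper_pct,spe_pct,spe_lower_pct,spe_upper_pct,n_pos,n_neg
testA,1,92.5,84.6,96.5,17.6,12.0,25.0,80,131
testA,2,90.0,81.5,94.8,29.0,21.9,37.3,80,131
testA,3,87.5,78.5,93.1,43.5,35.3,52.1,80,131
testA,4,82.5,72.7,89.3,58.0,49.4,66.1,80,131
testA,5,80.0,70.0,87.3,68.7,60.3,76.0,80,131
testA,6,76.3,65.9,84.3,77.9,70.1,84.2,80,131
testB,1,93.8,86.3,97.3,41.2,33.1,49.8,80,131
testB,2,88.8,80.0,94.0,54.2,45.7,62.5,80,131
testB,3,88.8,80.0,94.0,67.9,59.5,75.3,80,131
testB,4,81.3,71.4,88.3,80.2,72.6,86.1,80,131
testB,5,80.0,70.0,87.3,83.2,75.9,88.6,80,131
testB,6,72.5,61.9,81.1,87.0,80.2,91.7,80,131
testC,1,98.8,93.3,99.8,25.2,18.5,33.3,80,131
testC,2,98.8,93.3,99.8,36.6,28.8,45.1,80,131
testC,3,95.0,87.8,98.0,47.3,38.9,55.8,80,131
testC,4,95.0,87.8,98.0,51.9,43.4,60.3,80,131
testC,5,92.5,84.6,96.5,58.0,49.4,66.1,80,131
testC,6,83.8,74.2,90.3,71.8,63.6,78.8,80,131
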