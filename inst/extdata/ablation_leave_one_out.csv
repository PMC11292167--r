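dataset,relative_size,acc_segment_diff,acc_subject_diff,lme_p,t_segment_p,t_subject_p
ADARP,12.34,-2.44,-1.57,0.01,0.001,0.99
Stress Predict,0.30,-0.21,-1.57,0.23,0.99,0.99
Toadstool,0.04,0.52,-3.13,0.99,0.99,0.99
UE4W,2.32,-1.93,-4.70,0.99,0.003,0.99
WEEE,0.18,1.19,1.57,0.99,0.90,0.99
WESAD,0.42,-0.51,-1.57,0.99,0.99,0.99
WESD,0.72,1.90,1.57,0.06,0.05,0.99
In-GaugeEn-Gage,17.55,-4.44,-4.70,0.99,0.001,0.63
Nurse Stress Detection,11.82,-0.81,-1.57,0.99,0.99,0.99
BIG IDEAs Lab,19.38,-2.09,-1.57,0.99,0.08,0.99
PPG-DaLiA,0.69,1.93,4.70,0.53,0.001,0.99
TIMEBASE-INTREPIBD,34.24,-4.32,-3.13,0.99,0.99,0.38
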