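resampling_ratio,acc_segment_diff,acc_subject_diff,lme_p,t_segment_p,t_subject_p
80,-0.23,-1.57,0.09,0.001,0.001
60,-2.14,-1.57,0.07,0.001,0.001
40,-6.07,-4.70,0.06,0.001,0.001
20,-6.35,-4.70,0.05,0.001,0.001
0,-7.07,-7.82,0.04,0.001,0.001
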