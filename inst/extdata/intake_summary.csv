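drug,sex,hfd_g,chow_g,total_g,total_sem_g,preference_printed,preference_consistent
saline,F,4.26,0.09,4.35,0.10,0.98,TRUE
saline,M,2.44,0.79,3.23,0.67,0.96,FALSE
diethylpropion,F,0.35,0.14,0.48,0.12,0.71,TRUE
diethylpropion,M,0.23,0.08,0.30,0.12,0.62,FALSE
phentermine,F,0.22,0.12,0.34,0.08,0.65,TRUE
phentermine,M,0.03,0.21,0.24,0.11,0.19,FALSE
tesofensine,F,1.97,0.18,2.14,0.69,0.92,TRUE
tesofensine,M,0.70,0.03,0.72,0.51,0.80,FALSE
mazindol,F,2.24,0.23,2.46,0.58,0.91,TRUE
mazindol,M,1.78,0.19,1.97,0.24,0.89,TRUE
5-HTP,F,1.00,0.95,1.26,0.40,0.51,TRUE
5-HTP,M,0.28,0.96,1.23,0.28,0.23,TRUE
amphetamine,F,0.27,0.18,0.45,0.28,0.59,TRUE
amphetamine,M,0.17,0.02,0.18,0.10,0.47,FALSE
cathine,F,0.81,0.17,0.98,0.47,0.82,TRUE
cathine,M,0.36,0.39,0.75,0.40,0.67,FALSE
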