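drug,sex,mean_g,sd_g,cv_printed_pct
saline,F,13.25,9.44,71.27
saline,M,17.69,11.23,63.46
diethylpropion,F,-16.79,8.62,51.33
diethylpropion,M,-4.50,7.59,168.63
phentermine,F,-13.56,7.63,56.29
phentermine,M,-7.90,10.76,136.26
tesofensine,F,-11.88,9.68,81.53
tesofensine,M,-1.60,6.63,413.25
mazindol,F,-7.96,6.59,82.83
mazindol,M,-8.56,7.86,91.74
5-HTP,F,2.90,7.19,248.44
5-HTP,M,6.35,12.62,198.54
amphetamine,F,6.63,10.10,152.46
amphetamine,M,9.56,14.08,147.20
cathine,F,12.31,10.06,81.68
cathine,M,-11.08,8.72,78.70
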