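# Fitted BR-model release parameters for R6G-loaded PEGylated PLGA
# nanoparticles at three incubation temperatures (reference table, BR model).
parameter,unit,temperature_C,value
k_b,day^-1,37,1.8053
k_b,day^-1,47,2.2306
k_b,day^-1,57,2.7337
theta_b,-,37,0.5567
theta_b,-,47,0.5453
theta_b,-,57,0.6139
k_r,day^-1,37,0.1109
k_r,day^-1,47,0.1924
k_r,day^-1,57,0.3198
t_max,day,37,20.1849
t_max,day,47,9.5761
t_max,day,57,5.1626
theta_r,-,37,0.4433
theta_r,-,47,0.4547
theta_r,-,57,0.3861
r_squared,-,37,0.9929
r_squared,-,47,0.9963
r_squared,-,57,0.9931
r_squared_adjusted,-,37,0.9923
r_squared_adjusted,-,47,0.9960
r_squared_adjusted,-,57,0.9925
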