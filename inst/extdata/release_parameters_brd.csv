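# Fitted BRD-model release parameters for R6G-loaded PEGylated PLGA
# nanoparticles at three incubation temperatures (reference table, BRD model).
parameter,unit,temperature_C,value
k_b,day^-1,37,2.5244
k_b,day^-1,47,3.9805
k_b,day^-1,57,4.9721
theta_b,-,37,0.4636
theta_b,-,47,0.3988
theta_b,-,57,0.3945
k_r,day^-1,37,0.1274
k_r,day^-1,47,5.2914
k_r,day^-1,57,10.6848
t_max,day,37,27.2835
t_max,day,47,13.1061
t_max,day,57,8.5548
theta_r,-,37,0.2372
theta_r,-,47,0.0688
theta_r,-,57,2.6144e-9
D_e,cm^2 s^-1,37,3.4908e-18
D_e,cm^2 s^-1,47,4.7670e-18
D_e,cm^2 s^-1,57,9.2404e-18
theta_d,-,37,0.2992
theta_d,-,47,0.5324
theta_d,-,57,0.6055
r_squared,-,37,0.9889
r_squared,-,47,0.9931
r_squared,-,57,0.9944
r_squared_adjusted,-,37,0.9872
r_squared_adjusted,-,47,0.9920
r_squared_adjusted,-,57,0.9936
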