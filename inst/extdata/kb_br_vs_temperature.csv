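# Burst-rate constant k_b (day^-1) of the BR reference fit versus
# incubation temperature; example input for the `arrhenius` CLI subcommand.
temperature_C,value
37,1.8053
47,2.2306
57,2.7337
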