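protein,dh,dh_sd,minus_tds,minus_tds_sd,dg,dg_sd,dg_exp
PARP-1,-24.31,0.43,5.11,0.53,-19.20,0.48,-10.90
PARP-2,-22.29,0.43,6.13,0.83,-16.16,0.85,-7.90
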