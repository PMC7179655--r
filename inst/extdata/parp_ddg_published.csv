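protein,mutation,dd_e_vdw,dd_e_vdw_sd,dd_e_ele,dd_e_ele_sd,dd_g_gb,dd_g_gb_sd,dd_g_np,dd_g_np_sd,dd_h,dd_h_sd,minus_t_dd_s,minus_t_dd_s_sd,dd_g,dd_g_sd
PARP-1,Y907A,6.41,0.15,-0.09,0.19,-0.25,0.24,0.27,0.04,6.33,0.15,-0.73,0.13,5.60,0.26
PARP-1,Y889A,4.05,0.14,0.09,0.30,-0.04,0.26,0.24,0.02,4.35,0.18,-0.66,0.23,3.69,0.24
PARP-1,Y896A,3.33,0.09,0.90,0.05,-0.86,0.04,0.13,0.01,3.51,0.09,-0.41,0.05,3.10,0.13
PARP-1,H862A,1.53,0.16,-0.44,0.12,0.67,0.12,0.06,0.00,1.81,0.16,-0.17,0.04,1.64,0.19
PARP-1,E988A,1.04,0.13,4.94,0.11,-4.43,0.10,0.09,0.02,1.65,0.14,-0.28,0.11,1.37,0.25
PARP-1,E763A,1.20,0.21,4.90,0.28,-4.43,0.27,0.16,0.04,1.83,0.25,-0.87,0.29,0.96,0.23
PARP-1,K903A,1.38,0.21,-3.59,0.23,3.15,0.20,0.07,0.02,1.00,0.17,-0.13,0.05,0.87,0.16
PARP-1,D766A,0.19,0.08,4.00,0.21,-3.54,0.20,0.01,0.01,0.67,0.10,-0.15,0.08,0.52,0.03
PARP-1,V762A,0.56,0.03,-0.19,0.02,0.19,0.02,0.03,0.01,0.60,0.03,-0.11,0.03,0.49,0.05
PARP-1,Q759A,0.84,0.05,0.35,0.26,-0.41,0.23,0.05,0.02,0.83,0.04,-0.39,0.31,0.44,0.30
PARP-1,F897A,0.23,0.01,0.24,0.02,-0.18,0.03,0.00,0.00,0.30,0.02,-0.02,0.01,0.28,0.02
PARP-1,S904A,-0.55,0.29,1.87,0.29,-0.58,0.14,0.00,0.00,0.74,0.13,-0.46,0.14,0.28,0.21
PARP-1,W861A,0.06,0.00,-0.01,0.02,0.12,0.01,0.00,0.00,0.17,0.01,0.00,0.00,0.17,0.01
PARP-1,T887A,0.16,0.06,0.12,0.15,-0.09,0.13,0.01,0.00,0.20,0.09,-0.03,0.04,0.17,0.10
PARP-1,Y989A,0.07,0.01,-0.02,0.01,0.05,0.01,0.00,0.00,0.10,0.01,0.00,0.00,0.10,0.01
PARP-1,P885A,0.04,0.02,0.09,0.02,-0.08,0.02,0.00,0.00,0.05,0.02,-0.01,0.01,0.04,0.02
PARP-1,N987A,0.01,0.00,0.02,0.02,-0.02,0.02,0.00,0.00,0.01,0.00,0.00,0.00,0.01,0.00
PARP-1,S864A,0.03,0.01,-0.05,0.12,0.03,0.12,0.00,0.00,0.02,0.01,-0.02,0.02,0.00,0.02
PARP-2,Y473A,6.34,0.13,0.18,0.10,-0.55,0.11,0.34,0.01,6.31,0.12,-0.91,0.08,5.40,0.16
PARP-2,Y455A,3.35,0.70,0.32,0.25,-0.18,0.24,0.19,0.08,3.67,0.76,-0.53,0.19,3.14,0.58
PARP-2,Y462A,3.40,0.39,0.92,0.08,-0.94,0.07,0.16,0.05,3.54,0.40,-0.43,0.09,3.11,0.42
PARP-2,E558A,1.08,0.08,4.99,0.11,-4.46,0.11,0.11,0.02,1.71,0.09,-0.27,0.07,1.44,0.14
PARP-2,H428A,1.32,0.21,-0.10,0.31,0.29,0.31,0.06,0.01,1.57,0.25,-0.18,0.05,1.39,0.28
PARP-2,K469A,1.10,0.08,-3.41,0.07,3.00,0.07,0.09,0.01,0.77,0.08,-0.07,0.02,0.69,0.08
PARP-2,I331A,0.81,0.08,-0.31,0.12,0.31,0.04,0.08,0.05,0.88,0.12,-0.38,0.07,0.51,0.17
PARP-2,L327A,0.41,0.30,-0.02,0.07,0.06,0.07,0.04,0.03,0.49,0.31,-0.06,0.05,0.43,0.29
PARP-2,P451A,0.24,0.15,0.03,0.02,-0.01,0.03,0.02,0.02,0.28,0.17,-0.04,0.03,0.24,0.15
PARP-2,F463A,0.22,0.02,0.25,0.03,-0.22,0.04,0.00,0.00,0.25,0.04,-0.03,0.01,0.23,0.05
PARP-2,W427A,0.06,0.00,-0.01,0.02,0.12,0.02,0.00,0.00,0.17,0.01,0.00,0.00,0.17,0.01
PARP-2,S470A,-0.60,0.26,1.83,0.29,-0.61,0.11,0.00,0.00,0.63,0.10,-0.47,0.08,0.16,0.14
PARP-2,S328A,0.38,0.15,0.65,0.50,-0.73,0.51,0.05,0.04,0.35,0.16,-0.26,0.29,0.09,0.17
PARP-2,Y559A,0.06,0.01,-0.03,0.01,0.06,0.01,0.00,0.00,0.09,0.01,0.00,0.00,0.09,0.01
PARP-2,N557A,0.01,0.00,0.04,0.01,-0.04,0.01,0.00,0.00,0.01,0.00,0.00,0.00,0.01,0.00
PARP-2,Q332A,0.69,0.56,-0.39,1.11,0.26,1.15,0.07,0.08,0.64,0.57,-0.63,0.73,0.01,0.29
PARP-2,S430A,0.03,0.01,-0.02,0.07,0.01,0.07,0.00,0.00,0.02,0.01,-0.02,0.00,0.00,0.01
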