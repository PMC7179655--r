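protein,acceptor,donor,mean_distance,mean_angle,occupancy
PARP-1,NMS-P118 O28,H862 CA-HA,3.50,144.92,54.31
PARP-1,NMS-P118 F27,Q759 CB-HB3,3.08,126.79,77.93
PARP-1,NMS-P118 F26,Q759 CA-HA,3.68,134.10,27.08
PARP-2,NMS-P118 O28,H428 CA-HA,3.55,147.82,44.14
PARP-2,NMS-P118 F27,S328 CB-HB2,4.77,104.31,10.53
PARP-2,NMS-P118 F27,S328 CA-HA,3.91,123.98,25.61
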