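alternative	ACC	RCL	PRC	F1	SPC
.weights	0.4176	0.285	0.1453	0.0844	0.0676
SRAD	0.9271	0.9541	0.935	0.9444	0.8774
BH	0.8909	0.8654	0.9454	0.9036	0.9278
E4-L	0.8653	0.9363	0.7989	0.8622	0.8073
E4-R	0.8825	0.8974	0.8929	0.8951	0.8636
E4-(L+R)	0.9235	0.8833	0.9815	0.9298	0.9776
BH+E4-(L+R)	0.9564	0.9417	0.9831	0.962	0.9772
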