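alternative	ACC	RCL	PRC	F1	SPC
.weights	0.4176	0.285	0.1453	0.0844	0.0676
SRAD	0.9271	0.8774	0.9118	0.8942	0.9541
BH	0.8909	0.9278	0.8267	0.8743	0.8654
E4-L	0.8653	0.8072	0.9394	0.8683	0.9363
E4-R	0.8825	0.8636	0.8693	0.8664	0.8974
E4-(L+R)	0.9235	0.9776	0.8617	0.916	0.8833
BH+E4-(L+R)	0.9564	0.9772	0.9224	0.949	0.9417
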