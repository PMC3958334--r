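gene	screen1	screen2	screen3	screen4	screen5	screen6	interval	confidence
cnk	-1.02	0.03	-0.05	0.02	0.01	-0.02	RAS-RAF	0.62
Cdc37	-0.85	-0.78	-0.80	-0.91	0.04	0.02	RAF-MEK	0.35
mapk	-1.31	-1.22	-1.18	-1.25	-1.30	-1.27	MEK-MAPK	0.18
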