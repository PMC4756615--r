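# Built-in single-value (conformation-independent) backbone targets.
# Generic textbook-style protein backbone values; editable. Units:
# angstroms for lengths, degrees for angles. Glycine has no CB rows.
group	param	mean	sigma
General	N-CA	1.459	0.020
General	CA-C	1.525	0.026
General	C-O	1.229	0.019
General	CA-CB	1.532	0.020
General	C-N(+1)	1.336	0.023
General	C(-1)-N-CA	121.7	2.5
General	N-CA-C	111.0	2.7
General	N-CA-CB	110.6	1.8
General	CB-CA-C	110.4	2.0
General	CA-C-O	120.1	2.1
General	CA-C-N(+1)	117.2	2.2
General	O-C-N(+1)	122.7	1.6
Gly	N-CA	1.456	0.015
Gly	CA-C	1.514	0.016
Gly	C-O	1.232	0.016
Gly	C-N(+1)	1.326	0.018
Gly	C(-1)-N-CA	122.3	2.1
Gly	N-CA-C	113.1	2.5
Gly	CA-C-O	120.6	1.8
Gly	CA-C-N(+1)	116.2	2.0
Gly	O-C-N(+1)	123.2	1.7
Pro	N-CA	1.468	0.017
Pro	CA-C	1.524	0.020
Pro	C-O	1.228	0.020
Pro	CA-CB	1.531	0.020
Pro	C-N(+1)	1.338	0.019
Pro	C(-1)-N-CA	119.3	1.5
Pro	N-CA-C	112.1	2.6
Pro	N-CA-CB	103.0	1.1
Pro	CB-CA-C	111.7	2.1
Pro	CA-C-O	120.2	2.4
Pro	CA-C-N(+1)	117.1	2.8
Pro	O-C-N(+1)	121.1	1.9
IleVal	N-CA	1.459	0.020
IleVal	CA-C	1.525	0.026
IleVal	C-O	1.229	0.019
IleVal	CA-CB	1.540	0.027
IleVal	C-N(+1)	1.336	0.023
IleVal	C(-1)-N-CA	121.7	2.5
IleVal	N-CA-C	109.1	2.2
IleVal	N-CA-CB	111.5	1.7
IleVal	CB-CA-C	111.4	1.9
IleVal	CA-C-O	120.1	2.1
IleVal	CA-C-N(+1)	117.2	2.2
IleVal	O-C-N(+1)	122.7	1.6
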