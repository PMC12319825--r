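monkey	session	n_runs	pulses_per_run	tr_seconds
CH	1	31	301	2
CH	2	16	301	2
FE	1	8	305	2
FI	1	24	301	2
FI	2	11	301	2
IN	1	13	300	2
JA	1	41	422	1.4
JA	2	20	422	1.4
KA	1	23	301	2
KA	2	9	301	2
LA	1	20	301	2
LA	2	12	301	2
LE	1	21	300	2
LE	2	9	300	2
NA	1	37	422	1.4
NA	2	5	422	1.4
NA	3	13	422	1.4
TH	1	9	905	2
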