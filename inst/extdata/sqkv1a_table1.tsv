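transcript_id	position	ref_base	in_vivo_level	ctl_mean	ctl_sem	exp_mean	exp_sem
SqKv1A	44	A	0.27	0.00	0.00	0.00	0.00
SqKv1A	48	A	0.08	0.02	0.00	0.02	0.00
SqKv1A	63	A	0.20	0.02	0.00	0.04	0.01
SqKv1A	103	A	0.05	0.01	0.00	0.01	0.00
SqKv1A	107	A	0.48	0.02	0.00	0.02	0.00
SqKv1A	110	A	0.04	0.02	0.00	0.02	0.00
SqKv1A	127	A	0.52	0.02	0.00	0.02	0.00
SqKv1A	133	A	0.09	0.02	0.00	0.04	0.01
SqKv1A	134	A	0.69	0.01	0.00	0.78	0.34
SqKv1A	138	A	0.02	0.04	0.00	0.05	0.00
SqKv1A	139	A	0.15	0.02	0.00	0.11	0.04
SqKv1A	175	A	0.04	0.02	0.00	0.08	0.03
SqKv1A	190	A	0.02	0.01	0.00	0.09	0.03
SqKv1A	257	A	0.16	0.02	0.00	0.02	0.00
SqKv1A	259	A	0.60	0.03	0.00	0.03	0.00
SqKv1A	262	A	0.02	0.03	0.00	0.03	0.00
SqKv1A	361	A	0.02	0.03	0.00	0.03	0.00
SqKv1A	394	A	0.59	0.02	0.00	0.04	0.01
SqKv1A	395	A	0.21	0.02	0.01	0.04	0.01
SqKv1A	396	A	0.02	0.01	0.00	0.01	0.00
SqKv1A	418	A	0.94	0.04	0.01	10.33	4.87
SqKv1A	429	A	0.02	0.05	0.00	0.05	0.00
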