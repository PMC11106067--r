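t1	WNA,CA
t2	WNA
t3	WNA
t4	CA
t5	WNA
t6	EA
t7	ENA,JP,EU,EA,CA
t8	EA
t9	WNA,JP
t10	EA
t11	WNA
t12	EU,EA
t13	WNA
t14	WNA
t15	WNA
t16	ENA,EA
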