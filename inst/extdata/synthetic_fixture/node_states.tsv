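clade	range	corner_range
t1	WNA+CA	WNA
t2	WNA	WNA
t3	WNA	WNA
t4	CA	CA
t5	WNA	WNA
t6	EA	EA
t7	ENA+JP+EU+EA+CA	EA
t8	EA	EA
t9	WNA+JP	WNA
t10	EA	EA
t11	WNA	WNA
t12	EU+EA	EA
t13	WNA	WNA
t14	WNA	WNA
t15	WNA	WNA
t16	ENA+EA	EA
t1|t10|t11|t12|t13|t14|t15|t16|t2|t3|t4|t5|t6|t7|t8|t9	WNA	
t1|t11|t13|t15|t2|t3|t4|t5|t9	WNA	WNA
t10|t12|t14|t16|t6|t7|t8	WNA+EA	WNA
t10|t12|t16|t6|t7|t8	EA	EA
t10|t12|t16|t6|t8	EA	EA
t1|t11|t13|t15|t2|t4|t5	WNA+CA	WNA
t1|t4	WNA+CA	WNA+CA
t11|t13|t15|t2|t5	WNA	WNA
t10|t12|t6|t8	EA	EA
t11|t15|t2|t5	WNA	WNA
t3|t9	WNA	WNA
t11|t15|t2	WNA	WNA
t6|t8	EA	EA
t15|t2	WNA	WNA
t10|t12	EA	EA
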