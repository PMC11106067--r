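time_ma	type	scope	source	detail	node
23.11452157	dispersal	intercontinental	WNA	EA	19
19.14384323	vicariance	intercontinental	WNA+EA	EA | WNA	19
13.39685983	dispersal	adjacent	EA	JP	7
13.30101384	dispersal	intercontinental	EA	ENA	16
11.99534897	dispersal	intercontinental	JP+EA	ENA	7
 10.2674484	dispersal	intercontinental	ENA+JP+EA	EU	7
  9.0590843	dispersal	intercontinental	WNA	CA	22
7.262755537	vicariance	intercontinental	WNA+CA	CA | WNA	23
5.624595443	dispersal	intercontinental	WNA	JP	9
2.967143672	dispersal	adjacent	ENA+JP+EU+EA	CA	7
1.828580929	dispersal	intercontinental	WNA	CA	1
0.08570511324	dispersal	intercontinental	EA	EU	12
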