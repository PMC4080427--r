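id	t0	t1	t2	t3	t4	t5	t6	t7	t8	t9	t10	t11
tf1	0.583	0.504	0.492	0.588	0.581	0.503	-0.452	-0.433	-0.524	-0.408	-0.533	-0.45
tf2	0.587	0.547	0.544	0.596	0.428	0.478	0.562	0.401	0.487	0.578	0.469	0.535
tf3	-0.543	-0.573	-0.413	-0.577	-0.402	-0.419	-0.522	-0.558	-0.593	-0.472	-0.52	-0.566
g1	0.566	0.531	0.451	0.495	0.589	-0.511	-0.463	-0.419	-0.405	-0.406	-0.443	-0.548
g2	0.528	0.541	0.492	0.512	0.416	-0.433	-0.599	-0.478	-0.514	-0.476	-0.592	-0.497
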