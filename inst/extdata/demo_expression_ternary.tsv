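id	t0	t1	t2	t3	t4	t5	t6	t7	t8	t9	t10	t11
tf1	+	+	+	+	+	+	-	-	-	-	-	-
tf2	+	+	+	+	+	+	+	+	+	+	+	+
tf3	-	-	-	-	-	-	-	-	-	-	-	-
g1	+	+	+	+	+	-	-	-	-	-	-	-
g2	+	+	+	+	+	-	-	-	-	-	-	-
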