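##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-29
ustart1_ref	rtracklayer	gene	501	1870	.	+	.	ID=ustart1;
ustart1_ref	rtracklayer	mRNA	706	1870	.	+	.	ID=ustart1.a;Parent=ustart1
ustart1_ref	rtracklayer	exon	706	932	.	+	.	Parent=ustart1.a
ustart1_ref	rtracklayer	exon	984	1184	.	+	.	Parent=ustart1.a
ustart1_ref	rtracklayer	exon	1325	1546	.	+	.	Parent=ustart1.a
ustart1_ref	rtracklayer	exon	1602	1870	.	+	.	Parent=ustart1.a
ustart1_ref	rtracklayer	CDS	747	932	.	+	0	Parent=ustart1.a
ustart1_ref	rtracklayer	CDS	984	1184	.	+	0	Parent=ustart1.a
ustart1_ref	rtracklayer	CDS	1325	1546	.	+	0	Parent=ustart1.a
ustart1_ref	rtracklayer	CDS	1602	1829	.	+	0	Parent=ustart1.a
ustart1_ref	rtracklayer	mRNA	605	1870	.	+	.	ID=ustart1.b;Parent=ustart1
ustart1_ref	rtracklayer	exon	605	661	.	+	.	Parent=ustart1.b
ustart1_ref	rtracklayer	exon	984	1184	.	+	.	Parent=ustart1.b
ustart1_ref	rtracklayer	exon	1325	1546	.	+	.	Parent=ustart1.b
ustart1_ref	rtracklayer	exon	1602	1870	.	+	.	Parent=ustart1.b
ustart1_ref	rtracklayer	CDS	629	661	.	+	0	Parent=ustart1.b
ustart1_ref	rtracklayer	CDS	984	1184	.	+	0	Parent=ustart1.b
ustart1_ref	rtracklayer	CDS	1325	1546	.	+	0	Parent=ustart1.b
ustart1_ref	rtracklayer	CDS	1602	1829	.	+	0	Parent=ustart1.b
ustart1_ref	rtracklayer	mRNA	501	1870	.	+	.	ID=ustart1.c;Parent=ustart1
ustart1_ref	rtracklayer	exon	501	560	.	+	.	Parent=ustart1.c
ustart1_ref	rtracklayer	exon	984	1184	.	+	.	Parent=ustart1.c
ustart1_ref	rtracklayer	exon	1325	1546	.	+	.	Parent=ustart1.c
ustart1_ref	rtracklayer	exon	1602	1870	.	+	.	Parent=ustart1.c
ustart1_ref	rtracklayer	CDS	525	560	.	+	0	Parent=ustart1.c
ustart1_ref	rtracklayer	CDS	984	1184	.	+	0	Parent=ustart1.c
ustart1_ref	rtracklayer	CDS	1325	1546	.	+	0	Parent=ustart1.c
ustart1_ref	rtracklayer	CDS	1602	1829	.	+	0	Parent=ustart1.c
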