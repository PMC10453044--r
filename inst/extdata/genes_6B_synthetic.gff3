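##gff-version 3
##sequence-region 6B 1 700000000
6B	synthetic	gene	53800000	53802000	.	+	.	ID=SYNB6G000500;confidence=HC;description=Receptor kinase
6B	synthetic	gene	54419000	54421000	.	+	.	ID=SYNB6G000100;confidence=HC;description=uncharacterized protein
6B	synthetic	gene	55100000	55103500	.	+	.	ID=TraesCS6B02G079600;confidence=HC;description=Glycosyltransferase family 61 protein
6B	synthetic	gene	55900000	55905000	.	-	.	ID=TraesCS6B02G080100;confidence=HC;description=Sugar phosphate transferase
6B	synthetic	gene	56780000	56784200	.	+	.	ID=TraesCS6B02G080700;confidence=HC;description=Glycoside hydrolase family 32 protein
6B	synthetic	gene	56800000	56805300	.	+	.	ID=TraesCS6B02G080750;confidence=HC;description=Fructan 1-exohydrolase w3
6B	synthetic	gene	56830000	56834100	.	-	.	ID=TraesCS6B02G080800;confidence=HC;description=Glycoside hydrolase family 32 protein
6B	synthetic	gene	57500000	57502000	.	+	.	ID=SYNB6G000200;confidence=LC;description=uncharacterized protein
6B	synthetic	gene	58900000	58903000	.	+	.	ID=SYNB6G000300;confidence=HC;description=Cytochrome P450 oxidoreductase
6B	synthetic	gene	59600000	59602000	.	-	.	ID=SYNB6G000400;confidence=HC;description=DNA ligase 1
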