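model_id	patient_id	promoter_status	passage_a	protein_a	passage_b	protein_b
245127-232-R	245127	Non-methylated	3	Positive	4	Positive
466636-057-R	466636	Non-methylated	3	Positive	4	Positive
692163-330-T	692163	Non-methylated	3	Positive	4	Positive
779769-127-R	779769	Non-methylated	3	Positive	4	Positive
997726-040-R	997726	Methylated	3	Negative	4	Negative
BL0293-F563	BL0293	Methylated	4	Positive	5	Negative
BL0382-F1232	BL0382	Methylated	3	Positive	4	Positive
CN0375-F725	CN0375	Non-methylated	3	Positive	4	Positive
CN0446-F447	CN0446	Non-methylated	3	Positive	4	Positive
LG0556-F006	LG0556	Non-methylated	3	Positive	4	Positive
LG0567-F671	LG0567	Non-methylated	3	Positive	4	Positive
ST0110-F1568	ST0110	Non-methylated	3	Positive	4	Positive
LG0520-F434	LG0520	Non-methylated	3	Positive	4	Positive
235635-245-T	235635	Non-methylated	3	Positive	4	Positive
261386-189-R	261386	Non-methylated	3	Positive	4	Positive
283339-068-R	283339	Non-methylated	3	Positive	4	Positive
743489-274-T	743489	Non-methylated	3	Positive	4	Positive
743489-281-T	743489	Non-methylated	3	Positive	4	Positive
BL0269-F402	BL0269	Non-methylated	3	Positive	4	Positive
128128-338-R	128128	Non-methylated	3	Negative	4	Negative
172845-121-B	172845	Methylated	3	Negative	4	Negative
172845-121-T	172845	Methylated	3	Negative	4	Negative
172845-142-T	172845	Methylated	3	Positive	4	Positive
174941-126-T	174941	Non-methylated	3	Positive	4	Positive
248138-237-R	248138	Non-methylated	3	Positive	4	Positive
292921-168-R	292921	Non-methylated	3	Positive	4	Positive
327498-153-R	327498	Non-methylated	3	Positive	4	Positive
349418-098-R	349418	Non-methylated	3	Positive	4	Positive
521955-158-R2	521955	Non-methylated	3	Positive	4	Positive
521955-158-R3	521955	Non-methylated	3	Positive	4	Positive
521955-158-R4	521955	Non-methylated	3	Positive	4	Positive
521955-158-R6	521955	Non-methylated	3	Positive	4	Positive
521955-158-R7	521955	Non-methylated	3	Positive	4	Positive
563396-261-R	563396	Non-methylated	3	Positive	4	Positive
625472-104-R	625472	Methylated	3	Positive	4	Positive
782815-120-R	782815	Non-methylated	3	Positive	4	Positive
CN0330-F216	CN0330	Methylated	3	Negative	4	Negative
CN0428-F1126	CN0428	Non-methylated	3	Positive	4	Positive
LG0481-F231	LG0481	Non-methylated	3	Positive	4	Positive
LG1197-F385	LG1197	Non-methylated	3	Positive	4	Positive
172845-288-R	172845	Methylated	3	Positive	4	Positive
287614-091-R	287614	Non-methylated	3	Positive	4	Positive
692585-246-R	692585	Non-methylated	3	Positive	4	Positive
746718-042-R	746718	Non-methylated	3	Positive	4	Positive
997537-175-T	997537	Methylated	3	Positive	4	Positive
941425-263-T	941425	Non-methylated	3	Positive	4	Positive
952719-076-R	952719	Non-methylated	3	Positive	4	Positive
BL0479-F1894	BL0479	Methylated	3	Negative	4	Negative
SA0426-F1136	SA0426	Non-methylated	3	Positive	4	Positive
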