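model_id	diagnosis	tmz_response	combo_response	promoter_status	protein_expression
128128-338-R	Melanoma	No response	Response	Non-methylated	Negative
172845-121-B	Colon adenocarcinoma	No response	Response	Methylated	Negative
172845-121-T	Colon adenocarcinoma	No response	Response	Methylated	Negative
692163-330-T	Uterine leiomyosarcoma	No response	Response	Non-methylated	Positive
997726-040-R	Lung squamous cell carcinoma	Response	Response	Methylated	Negative
BL0293-F563	Urothelial/bladder cancer	Response	Response	Methylated	Positive & Negative
BL0382-F1232	Urothelial/bladder cancer	No response	Response	Methylated	Positive
CN0330-F216	Colon adenocarcinoma	Response	Response	Methylated	Negative
LG0520-F434	Lung squamous cell carcinoma	Response	Response	Non-methylated	Positive
SA0426-F1136	Non-uterine leiomyosarcoma	Response	Response	Non-methylated	Positive
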