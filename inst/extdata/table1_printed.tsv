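cancer	species	mr	quantity	printed	excluded
colorectal	-	FALSE	u_baseline	4.0e-6	FALSE
colorectal	-	TRUE	u_baseline	2.5e-6	FALSE
hepatocellular	-	FALSE	u_baseline	8.2e-7	FALSE
hepatocellular	-	TRUE	u_baseline	5.2e-7	FALSE
esophageal	-	FALSE	u_baseline	4.0e-6	FALSE
esophageal	-	TRUE	u_baseline	2.6e-6	FALSE
colorectal	African elephant	FALSE	M_add	3.6	FALSE
colorectal	African elephant	FALSE	u_fold	36	FALSE
colorectal	Florida manatee	FALSE	M_add	2.3	FALSE
colorectal	Florida manatee	FALSE	u_fold	13	FALSE
colorectal	human	FALSE	M_add	2.3	FALSE
colorectal	human	FALSE	u_fold	11	FALSE
colorectal	African elephant	TRUE	M_add	1.5	TRUE
colorectal	African elephant	TRUE	u_fold	12	FALSE
colorectal	Florida manatee	TRUE	M_add	1.4	TRUE
colorectal	Florida manatee	TRUE	u_fold	6	FALSE
colorectal	human	TRUE	M_add	0.9	TRUE
colorectal	human	TRUE	u_fold	7	FALSE
hepatocellular	African elephant	FALSE	M_add	1.1	FALSE
hepatocellular	African elephant	FALSE	u_fold	217	FALSE
hepatocellular	Florida manatee	FALSE	M_add	0.7	FALSE
hepatocellular	Florida manatee	FALSE	u_fold	46	FALSE
hepatocellular	human	FALSE	M_add	0.6	FALSE
hepatocellular	human	FALSE	u_fold	22	FALSE
hepatocellular	African elephant	TRUE	M_add	0.7	TRUE
hepatocellular	African elephant	TRUE	u_fold	74	FALSE
hepatocellular	Florida manatee	TRUE	M_add	0.5	TRUE
hepatocellular	Florida manatee	TRUE	u_fold	21	FALSE
hepatocellular	human	TRUE	M_add	0.4	TRUE
hepatocellular	human	TRUE	u_fold	14	FALSE
esophageal	African elephant	FALSE	M_add	2.2	TRUE
esophageal	African elephant	FALSE	u_fold	65	FALSE
esophageal	Florida manatee	FALSE	M_add	1.7	FALSE
esophageal	Florida manatee	FALSE	u_fold	19	FALSE
esophageal	human	FALSE	M_add	1.6	FALSE
esophageal	human	FALSE	u_fold	14	FALSE
esophageal	African elephant	TRUE	M_add	1.3	TRUE
esophageal	African elephant	TRUE	u_fold	22	FALSE
esophageal	Florida manatee	TRUE	M_add	0.8	TRUE
esophageal	Florida manatee	TRUE	u_fold	9	FALSE
esophageal	human	TRUE	M_add	0.9	TRUE
esophageal	human	TRUE	u_fold	9	FALSE
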