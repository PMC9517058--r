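# cagekin system fixtures, version 1
# Long-format table of per-system quantities for the four studied systems:
# the free amide in solution (sol), mono-encapsulation (2in1), the
# encapsulated amide dimer (2_2in1) and amide + co-guest (2.3in1).
# provenance: table1 / table2 = transcribed printed values;
#             prose = stated in the source text, not in a table;
#             synthetic = package defaults with no printed counterpart
#             (solvent-contact counts NW and the populations of the twisted
#             conformers are published only as figures).
system_id	conformer	quantity	value	units	provenance
sol	NA	dG_conf	6.5	kcal/mol	table1
sol	NA	K_conf	1.8e-5	1	table1
sol	NA	barrier_conf	22.3	kcal/mol	table1
sol	NA	t_trans_cis	3.5e3	s	table1
sol	NA	t_cis_trans	1.4e-1	s	table1
2in1	NA	dG_conf	5.0	kcal/mol	table1
2in1	NA	K_conf	2.3e-4	1	table1
2in1	NA	barrier_conf	22.0	kcal/mol	table1
2in1	NA	t_trans_cis	2.3e3	s	table1
2in1	NA	t_cis_trans	1.6e0	s	table1
2_2in1	NA	dG_conf	4.0	kcal/mol	table1
2_2in1	NA	K_conf	1.2e-3	1	table1
2_2in1	NA	barrier_conf	25.9	kcal/mol	table1
2_2in1	NA	t_trans_cis	1.5e6	s	table1
2_2in1	NA	t_cis_trans	4.7e2	s	table1
2.3in1	NA	dG_conf	2.7	kcal/mol	table1
2.3in1	NA	K_conf	1.1e-2	1	table1
2.3in1	NA	barrier_conf	19.8	kcal/mol	table1
2.3in1	NA	t_trans_cis	5.4e1	s	table1
2.3in1	NA	t_cis_trans	1.4e0	s	table1
2in1	trans	dG_enc	-4.3	kcal/mol	table2
2in1	trans	K_enc	1.5e3	1	table2
2in1	trans	barrier_enc	13.5	kcal/mol	table2
2in1	trans	t_off	1.2e-3	s	table2
2in1	trans	k_off	8.3e2	1/s	table2
2in1	trans	k_on	1.3e6	1/s	table2
2in1	cis	dG_enc	-7.4	kcal/mol	table2
2in1	cis	K_enc	2.1e5	1	table2
2in1	cis	barrier_enc	14.9	kcal/mol	table2
2in1	cis	t_off	1.4e-2	s	table2
2in1	cis	k_off	7.1e1	1/s	table2
2in1	cis	k_on	1.8e7	1/s	table2
2_2in1	trans	dG_enc	-4.7	kcal/mol	table2
2_2in1	trans	K_enc	2.7e3	1	table2
2_2in1	trans	barrier_enc	14.5	kcal/mol	table2
2_2in1	trans	t_off	7.3e-3	s	table2
2_2in1	trans	k_off	1.4e2	1/s	table2
2_2in1	trans	k_on	3.7e5	1/s	table2
2_2in1	cis	dG_enc	-9.3	kcal/mol	table2
2_2in1	cis	K_enc	6.9e6	1	table2
2_2in1	cis	barrier_enc	16.7	kcal/mol	table2
2_2in1	cis	t_off	9.6e-1	s	table2
2_2in1	cis	k_off	1.0e0	1/s	table2
2_2in1	cis	k_on	7.1e6	1/s	table2
2.3in1	trans	dG_enc	-4.5	kcal/mol	table2
2.3in1	trans	K_enc	2.2e3	1	table2
2.3in1	trans	barrier_enc	13.8	kcal/mol	table2
2.3in1	trans	t_off	2.2e-3	s	table2
2.3in1	trans	k_off	4.5e2	1/s	table2
2.3in1	trans	k_on	1.0e6	1/s	table2
2.3in1	cis	dG_enc	-11.1	kcal/mol	table2
2.3in1	cis	K_enc	1.3e8	1	table2
2.3in1	cis	barrier_enc	19.1	kcal/mol	table2
2.3in1	cis	t_off	1.7e1	s	table2
2.3in1	cis	k_off	5.9e-2	1/s	table2
2.3in1	cis	k_on	7.7e6	1/s	table2
sol	trans	nw	2.5	count	synthetic
sol	cis	nw	2.0	count	synthetic
sol	pi4	nw	2.0	count	synthetic
sol	pi2	nw	2.0	count	synthetic
2in1	trans	nw	1.2	count	synthetic
2in1	cis	nw	0.9	count	synthetic
2in1	pi4	nw	0.9	count	synthetic
2in1	pi2	nw	0.9	count	synthetic
2_2in1	trans	nw	0.9	count	synthetic
2_2in1	cis	nw	0.8	count	synthetic
2_2in1	pi4	nw	0.8	count	synthetic
2_2in1	pi2	nw	0.8	count	synthetic
2.3in1	trans	nw	0.6	count	synthetic
2.3in1	cis	nw	1.1	count	synthetic
2.3in1	pi4	nw	1.1	count	synthetic
2.3in1	pi2	nw	1.1	count	synthetic
sol	pi4	pconf	1.0e-9	1	synthetic
2in1	pi4	pconf	1.0e-8	1	synthetic
2_2in1	pi4	pconf	3.0e-8	1	synthetic
2.3in1	pi4	pconf	1.0e-6	1	synthetic
sol	pi2	pconf	1.0e-16	1	synthetic
2in1	pi2	pconf	1.0e-15	1	synthetic
2_2in1	pi2	pconf	3.0e-15	1	synthetic
2.3in1	pi2	pconf	1.0e-13	1	synthetic
all	trans	chi	1.0e-9	1	prose
all	cis	chi	1.0e-3	1	prose
all	pi4	chi	1.0e0	1	prose
all	pi2	chi	1.0e0	1	synthetic
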