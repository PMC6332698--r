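# SYNTHETIC amyloid hexapeptide position-specific scoring matrix.
# Stand-in for a published amyloid hexapeptide PSSM (which cannot be
# redistributed here): built from the canonical beta-aggregation propensity
# ordering of the 20 residues (I/V/F/Y/W/L high; P/K/E/D/G low) with
# asymmetric position dependence (central positions weighted up, proline
# penalised mid-core, glycine tolerated at the ends).
# Rows: hexapeptide positions 1-6; columns: residues. Dimensionless.
# anchors line: minimum and maximum achievable hexapeptide sums.
pos	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
1	0.2800	0.9800	-1.1200	-1.1900	1.6100	-0.0500	-0.1400	1.5400	-1.2600	1.2600	0.8400	0.2100	-2.1000	0.1400	-0.9800	0.0700	0.3500	1.4000	1.1900	1.3300
2	0.4000	1.4000	-1.6000	-1.7000	2.3000	-0.5000	-0.2000	2.2000	-1.8000	1.8000	1.2000	0.3000	-3.5000	0.2000	-1.4000	0.1000	0.5000	2.0000	1.7000	1.9000
3	0.5000	1.7500	-2.0000	-2.1250	2.8750	-0.6250	-0.2500	2.7500	-2.2500	2.2500	1.5000	0.3750	-4.2500	0.2500	-1.7500	0.1250	0.6250	2.5000	2.1250	2.3750
4	0.4600	1.6100	-1.8400	-1.9550	2.6450	-0.5750	-0.2300	2.5300	-2.0700	2.0700	1.3800	0.3450	-3.9500	0.2300	-1.6100	0.1150	0.5750	2.3000	1.9550	2.1850
5	0.3800	1.3300	-1.5200	-1.6150	2.1850	-0.4750	-0.1900	2.0900	-1.7100	1.7100	1.1400	0.2850	-3.3500	0.1900	-1.3300	0.0950	0.4750	1.9000	1.6150	1.8050
6	0.2600	0.9100	-1.0400	-1.1050	1.4950	-0.0250	-0.1300	1.4300	-1.1700	1.1700	0.7800	0.1950	-1.9500	0.1300	-0.9100	0.0650	0.3250	1.3000	1.1050	1.2350
anchors	-19.1000	13.1100
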