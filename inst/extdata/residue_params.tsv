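# Residue neutron scattering parameters (version 1, generated from atomic compositions).
# b_h: summed coherent scattering length, all H protiated, Angstrom.
# b_d: same with all labile (N-H/O-H/S-H) hydrogens exchanged to 2H, Angstrom.
# Element coherent scattering lengths (NIST): H -3.739, D 6.671, C 6.6460, N 9.36, O 5.803, S 2.804 fm.
# V: consensus residue volume (Zamyatnin lineage), Angstrom^3.  mass: average residue mass, Da.
# Convention: Asp/Glu neutral (COOH), Lys/Arg/His neutral side chains; Pro has no labile H.
code	nC	nH	nN	nO	nS	n_labile	V	mass	b_h	b_d
ALA	3	5	1	1	0	1	88.6	71.08	0.00016406	0.00026816
ARG	6	12	4	1	0	5	173.4	156.19	0.00038251	0.00090301
ASN	4	6	2	2	0	3	114.1	114.10	0.00034476	0.00065706
ASP	4	5	1	3	0	2	111.1	115.09	0.00034658	0.00055478
CYS	3	5	1	1	1	2	108.5	103.14	0.00019210	0.00040030
GLN	5	8	2	2	0	3	143.8	128.13	0.00033644	0.00064874
GLU	5	7	1	3	0	2	138.4	129.12	0.00033826	0.00054646
GLY	2	3	1	1	0	1	60.1	57.05	0.00017238	0.00027648
HIS	6	7	3	1	0	2	153.2	137.14	0.00047586	0.00068406
ILE	6	11	1	1	0	1	166.7	113.16	0.00013910	0.00024320
LEU	6	11	1	1	0	1	166.7	113.16	0.00013910	0.00024320
LYS	6	12	2	1	0	3	168.6	128.17	0.00019531	0.00050761
MET	5	9	1	1	1	1	162.9	131.19	0.00017546	0.00027956
PHE	9	9	1	1	0	1	189.9	147.18	0.00041326	0.00051736
PRO	5	7	1	1	0	0	112.7	97.12	0.00022220	0.00022220
SER	3	5	1	2	0	2	89.0	87.08	0.00022209	0.00043029
THR	4	7	1	2	0	2	116.1	101.10	0.00021377	0.00042197
TRP	11	10	2	1	0	2	227.8	186.21	0.00060239	0.00081059
TYR	9	9	1	2	0	2	193.6	163.18	0.00047129	0.00067949
VAL	5	9	1	1	0	1	140.0	99.13	0.00014742	0.00025152
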