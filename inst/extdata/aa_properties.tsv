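# Default per-amino-acid property scales (one row per standard residue).
# Columns (published scale used for each category):
#   composition   - relative occurrence of the residue in proteins (%%), Dayhoff et al. 1978 (AAindex DAYM780101)
#   flexibility   - average flexibility index, Bhaskaran & Ponnuswamy 1988 (AAindex BHAR880101)
#   hydrophobicity- hydropathy index, Kyte & Doolittle 1982 (AAindex KYTJ820101)
#   net_charge    - net charge at pH 7, Klein et al. 1984 (AAindex KLEP840101)
#   partition     - octanol/water hydrophobic parameter pi, Fauchere & Pliska 1983 (AAindex FAUJ830101)
#   volume        - residue volume in cubic Angstrom, Zamyatnin 1972
#   mol_weight    - residue (monomer minus water) molecular weight, Da
#   asa           - maximum solvent-accessible surface area in square Angstrom, Tien et al. 2013 (theoretical)
# Values are raw; encoders min-max normalise each scale to [0,1] over the 20 residues.
# Override with a user-supplied table of the same layout.
aa	composition	flexibility	hydrophobicity	net_charge	partition	volume	mol_weight	asa
A	8.6	0.357	1.8	0	0.31	88.6	71.08	129
C	2.9	0.346	2.5	0	1.54	108.5	103.14	167
D	5.5	0.511	-3.5	-1	-0.77	111.1	115.09	193
E	6.0	0.497	-3.5	-1	-0.64	138.4	129.12	223
F	3.6	0.314	2.8	0	1.79	189.9	147.18	240
G	8.4	0.544	-0.4	0	0.00	60.1	57.05	104
H	2.0	0.323	-3.2	0	0.13	153.2	137.14	224
I	4.5	0.462	4.5	0	1.80	166.7	113.16	197
K	6.6	0.466	-3.9	1	-0.99	168.6	128.17	236
L	7.4	0.365	3.8	0	1.70	166.7	113.16	201
M	1.7	0.295	1.9	0	1.23	162.9	131.19	224
N	4.3	0.463	-3.5	0	-0.60	114.1	114.10	195
P	5.2	0.509	-1.6	0	0.72	112.7	97.12	159
Q	3.9	0.493	-3.5	0	-0.22	143.8	128.13	225
R	4.9	0.529	-4.5	1	-1.01	173.4	156.19	274
S	7.0	0.507	-0.8	0	-0.04	89.0	87.08	155
T	6.1	0.444	-0.7	0	0.26	116.1	101.10	172
V	6.6	0.386	4.2	0	1.22	140.0	99.13	174
W	1.3	0.305	-0.9	0	2.25	227.8	186.21	285
Y	3.4	0.420	-1.3	0	0.96	193.6	163.18	263
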