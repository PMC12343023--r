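# Distance-based bond assignment table for H/C/N/O/F.
# Reference bond lengths (Angstroms) are standard covalent values; a pair at
# distance d receives the highest order whose window [length - margin,
# length + margin] contains d. Margins are per-(pair, order), chosen so that
# windows of adjacent orders of the same pair do not overlap beyond their
# boundary. The C-O triple bond (carbon monoxide only) is excluded: its
# reference (1.13 A) cannot be separated from C=O (1.20 A) at window
# resolution. Edit or replace this file to change the metric's chemistry.
elem1	elem2	order	length	margin
H	H	1	0.74	0.25
H	C	1	1.09	0.25
H	N	1	1.01	0.22
H	O	1	0.96	0.22
H	F	1	0.92	0.20
C	C	1	1.54	0.12
C	C	2	1.34	0.10
C	C	3	1.20	0.06
C	N	1	1.47	0.10
C	N	2	1.29	0.08
C	N	3	1.16	0.05
C	O	1	1.43	0.10
C	O	2	1.20	0.10
C	F	1	1.35	0.20
N	N	1	1.45	0.08
N	N	2	1.25	0.07
N	N	3	1.10	0.06
N	O	1	1.40	0.08
N	O	2	1.21	0.07
N	F	1	1.36	0.15
O	O	1	1.48	0.10
O	O	2	1.21	0.08
O	F	1	1.42	0.15
F	F	1	1.42	0.15
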