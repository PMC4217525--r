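# Calcium buffers and indicator dyes used in microdomain simulations.
# Units: B_T_uM in uM, k_plus in uM^-1 ms^-1, k_minus in ms^-1.
# CV is metadata from the source table (no reference volume stated);
# "<0.000" entries are stored as NA.
name	B_T_uM	k_plus	k_minus	CV	reference
CaM	24	0.1	0.038	0.001	Smith et al. 1996
TnC	140	0.12	0.023	NA	Uttenweiler et al. 1998
PV	1000	0.25	0.001	NA	Jiang et al. 1999
EGTA	100	0.0015	0.00094	NA	Uttenweiler et al. 1998
Fluo-4	100	0.236	0.175	NA	Uttenweiler et al. 1998
OGB-5N	100	0.17	5.6	NA	Novo et al. 1999
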