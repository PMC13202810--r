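ligand	receptor	category
PTPRM	PTPRM	adhesion_junction
NEGR1	NEGR1	adhesion_junction
NCAM1	NCAM1	adhesion_junction
CD99	CD99	adhesion_junction
THBS1	CD36	metabolic
COL4A1	CD44	ecm_adhesive
COL4A2	CD44	ecm_adhesive
IGF2	IGF1R	growth_factor
IGF2	IGF2R	growth_factor
COL4A2	SDC4	ecm_structural
FN1	SDC4	ecm_structural
COL6A2	SDC4	ecm_adhesive
THBS3	SDC4	ecm_adhesive
JAG2	NOTCH2	notch
DLL1	NOTCH2	notch
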