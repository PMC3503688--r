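symbol	locus_tag
XYL1	PICST_89614
XYL2	PICST_86924
XKS1	PICST_68734
PGI1	PICST_84923
TAL1	PICST_74289
ADH3	PICST_88760
GDH3	PICST_82969
ALA2	PICST_70108
GLY1	PICST_7413
GLY2	PICST_71203
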