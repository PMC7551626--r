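module	signature	substrate	brackets	source
NcpA1	DASTIAAVC	Tyr	299	N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpA2	DILQLGLIW	Gly		N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpA3	DAWQFGLID	Gln		N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpB1	DAFFLGVTF	Ile/Val		N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpB2	DVWHISLID	Ser		N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpB3	DVQFIAHVA	Pro/MePro	278	N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
NcpB4	DAWTIGAVC	Phe/Tyr/Leu	278,322	N. edaphicum CCNP1411 ncpA/ncpB binding-pocket residues (GrsA numbering 235,236,239,278,299,301,322,330,331)
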