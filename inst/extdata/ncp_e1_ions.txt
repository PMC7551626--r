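# published unit-resolution product-ion list, cyclic imine Ncp-E1 (cyclo[Tyr+Gly+Gln+Ile+Ser+Pro+Phe]), [M+H]+ 777
777 1
759 1
741 1
690 1
672 1
662 1
646 1
628 1
575 1
549 1
480 1
462 1
444 1
434 1
392 1
352 1
335 1
316 1
307 1
298 1
229 1
201 1
158 1
132 1
70 1
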