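# published unit-resolution product-ion list, linear aldehyde Ncp-E1-L (Tyr+Gly+Gln+Ile+Ser+Pro+Phe), [M+H]+ 795
795 1
777 1
759 1
646 1
614 1
575 1
549 1
531 1
462 1
349 1
334 1
247 1
229 1
201 1
148 1
136 1
129 1
101 1
84 1
70 1
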