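# published unit-resolution product-ion list, linear free-acid hexapeptide Ncp-E4-L (Tyr+Gly+Gln+Ile+Ser+MePro)
677 1
659 1
642 1
549 1
531 1
521 1
462 1
434 1
349 1
329 1
312 1
221 1
193 1
148 1
136 1
129 1
101 1
86 1
84 1
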