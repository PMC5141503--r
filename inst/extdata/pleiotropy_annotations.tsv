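rsid	trait_tag
rs724577	height
rs1042725	height
rs1801253	blood_pressure
rs6931514	t2d
rs9883204	t2d
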