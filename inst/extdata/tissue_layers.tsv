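tissue	abbrev	layer
Adipose Tissue	AT	ectoderm
Blood	Bl	mesoderm
Frontal Cortex	FC	ectoderm
Kidney	Ki	mesoderm
Liver	Li	endoderm
Lung	Lu	mesoderm
Motor Cortex	MC	ectoderm
Pancreas	Pa	endoderm
Skeletal Muscle	SM	mesoderm
Skin	Sk	ectoderm
Small Intestine	SI	endoderm
Spinal Cord	SpC	ectoderm
Spleen	Sp	mesoderm
Suprarrenal Cortex	SuC	mesoderm
Testes	Te	mesoderm
Thyroid	Th	endoderm
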