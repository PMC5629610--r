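carcinoma	cancer
cancer	carcinoma
tumour	tumor
tumor	tumour
neoplasm	tumor
disorder	disease
disease	disorder
kidney	renal
renal	kidney
cardiac	heart
heart	cardiac
hepatic	liver
liver	hepatic
pulmonary	lung
lung	pulmonary
haemorrhage	hemorrhage
hemorrhage	haemorrhage
anaemia	anemia
anemia	anaemia
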