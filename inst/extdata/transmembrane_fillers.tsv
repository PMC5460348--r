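cargo	membrane	def_dbxref
leucine	plasma membrane	PMID:1|GOC:dos
glycine	plasma membrane	PMID:2
serine	plasma membrane
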