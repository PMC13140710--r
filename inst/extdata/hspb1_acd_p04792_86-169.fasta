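>sp|P04792|86-169 HspB1 (Hsp27) alpha-crystallin domain, human HSPB1 residues 86-169
SEIRHTADRWRVSLDVNHFAPDELTVKTKDGVVEITGKHEERQDEHGYISRCFTRKYTLP
PGVDPTQVSSSLSPEGTLTVEAPM
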