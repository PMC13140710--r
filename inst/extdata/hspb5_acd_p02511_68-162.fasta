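>sp|P02511|68-162 HspB5 (alphaB-crystallin) alpha-crystallin domain, human CRYAB residues 68-162
MRLEKDRFSVNLDVKHFSPEELKVKVLGDVIEVHGKHEERQDEHGFISREFHRKYRIPAD
VDPLTITSSLSSDGVLTVNGPRKQVSGPERTIPIT
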