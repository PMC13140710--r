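>sp|Q13148|267-414 TDP-43 low-complexity domain, human TARDBP residues 267-414
NRQLERSGRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGSNMGGGMNFGAFSINPAMMAAA
QAALQSSWGMMGMLASQQNQSGPSGNNQNQGNMQREPNQAFGSGNNSYSGSNSGAAIGWG
SASNAGSGSGFNGGFGSSMDSKSSGWGM
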