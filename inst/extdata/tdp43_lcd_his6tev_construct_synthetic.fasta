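>tdp43_lcd_his6tev_construct synthetic reconstruction: vector-encoded His6-TEV leader (exact linker not public; only its TEV-site Tyr carries absorbance) fused to Q13148 residues 267-414
MGSSHHHHHHSSGENLYFQGSNRQLERSGRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGS
NMGGGMNFGAFSINPAMMAAAQAALQSSWGMMGMLASQQNQSGPSGNNQNQGNMQREPNQ
AFGSGNNSYSGSNSGAAIGWGSASNAGSGSGFNGGFGSSMDSKSSGWGM
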