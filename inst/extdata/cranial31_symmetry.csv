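landmark,side,pair_name
nasion,midplane,
glabella,midplane,
frontozygomaticorbitale_R,right,frontozygomaticorbitale
frontozygomaticorbitale_L,left,frontozygomaticorbitale
frontomalare_R,right,frontomalare
frontomalare_L,left,frontomalare
alare_R,right,alare
alare_L,left,alare
zygomaxillare_R,right,zygomaxillare
zygomaxillare_L,left,zygomaxillare
dacryon_R,right,dacryon
dacryon_L,left,dacryon
nasomaxillary_R,right,nasomaxillary
nasomaxillary_L,left,nasomaxillary
ectomolare_R,right,ectomolare
ectomolare_L,left,ectomolare
jugale_R,right,jugale
jugale_L,left,jugale
porion_R,right,porion
porion_L,left,porion
asterion_R,right,asterion
asterion_L,left,asterion
lambda,midplane,
bregma,midplane,
opisthion,midplane,
basion,midplane,
mastoidale_R,right,mastoidale
mastoidale_L,left,mastoidale
zygion_R,right,zygion
zygion_L,left,zygion
prosthion,midplane,
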