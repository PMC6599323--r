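strain,analyte,mean,sd,n,unit
WT,total_GA,1.21,0.09,3,mg/100mg DW
WT,GA-Mk,2,0,3,ug/100mg DW
WT,GA-T,18,1,3,ug/100mg DW
WT,GA-S,8,1,3,ug/100mg DW
WT,GA-Me,10,1,3,ug/100mg DW
FPS1,total_GA,2.76,0.38,3,mg/100mg DW
FPS1,GA-Mk,4,1,3,ug/100mg DW
FPS1,GA-T,41,2,3,ug/100mg DW
FPS1,GA-S,21,5,3,ug/100mg DW
FPS1,GA-Me,28,1,3,ug/100mg DW
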