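ligase,library,High_Affinity,Low_Affinity,No_Affinity
CRBN,ChEMBL,4834,7448,36
CRBN,Vitas,1748,11949,73
MDM2,ChEMBL,131,51,0
MDM2,Vitas,2302,11361,86
VHL,ChEMBL,8792,3414,80
VHL,Vitas,6607,6949,137
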