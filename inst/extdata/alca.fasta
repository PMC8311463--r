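>alca1 topology=cyclic cys_state=oxidized disulfides=3
GVIPCGESCVFIPCISAAIGCSCKNKVCYRD
>alca2 topology=cyclic cys_state=oxidized disulfides=3
GIPCGESCVFIPCISGVLGCSCSNKVCYRN
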