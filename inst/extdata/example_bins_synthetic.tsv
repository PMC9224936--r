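pos001	MAG01
pos002	MAG02
pos003	MAG03
pos004	MAG01
abl001	MAG02
abl002	MAG03
far001	MAG01
far002	MAG02
shf001	MAG03
shf002	MAG01
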