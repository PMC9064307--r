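stage,older,younger
Induan,251.902,251.2
Olenekian,251.2,247.2
Anisian,247.2,242
Ladinian,242,237
Carnian,237,227
Norian,227,208.5
Rhaetian,208.5,201.4
Hettangian,201.4,199.5
Sinemurian,199.5,192.9
Pliensbachian,192.9,184.2
Toarcian,184.2,174.7
Aalenian,174.7,170.9
Bajocian,170.9,168.2
Bathonian,168.2,165.3
Callovian,165.3,161.5
Oxfordian,161.5,154.8
Kimmeridgian,154.8,149.2
Tithonian,149.2,145
Berriasian,145,139.8
Valanginian,139.8,132.6
Hauterivian,132.6,125.77
Barremian,125.77,121.4
Aptian,121.4,113
Albian,113,100.5
Cenomanian,100.5,93.9
Turonian,93.9,89.8
Coniacian,89.8,86.3
Santonian,86.3,83.6
Campanian,83.6,72.1
Maastrichtian,72.1,66
Danian,66,61.6
Selandian,61.6,59.2
Thanetian,59.2,56
Ypresian,56,47.8
Lutetian,47.8,41.2
Bartonian,41.2,37.71
Priabonian,37.71,33.9
Rupelian,33.9,27.82
Chattian,27.82,23.03
Aquitanian,23.03,20.44
Burdigalian,20.44,15.97
Langhian,15.97,13.82
Serravallian,13.82,11.63
Tortonian,11.63,7.246
Messinian,7.246,5.333
Zanclean,5.333,3.6
Piacenzian,3.6,2.58
Gelasian,2.58,1.8
Calabrian,1.8,0.774
Chibanian,0.774,0.129
Late Pleistocene,0.129,0.0117
Holocene,0.0117,0
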