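name,older_ma,younger_ma
Induan,251.9,251.2
Olenekian,251.2,247.2
Anisian,247.2,242.0
Ladinian,242.0,237.0
Carnian,237.0,227.0
Norian,227.0,208.5
Rhaetian,208.5,201.4
Hettangian,201.4,199.3
Sinemurian,199.3,192.9
Pliensbachian,192.9,184.2
Toarcian,184.2,174.7
Aalenian,174.7,170.9
Bajocian,170.9,168.2
Bathonian,168.2,165.3
Callovian,165.3,161.5
Oxfordian,161.5,154.8
Kimmeridgian,154.8,149.2
Tithonian,149.2,143.1
Berriasian,143.1,137.7
Valanginian,137.7,132.6
Hauterivian,132.6,125.8
Barremian,125.8,121.4
Aptian,121.4,113.2
Albian,113.2,100.5
Cenomanian,100.5,93.9
Turonian,93.9,89.8
Coniacian,89.8,86.3
Santonian,86.3,83.6
Campanian,83.6,72.1
Maastrichtian,72.1,66.0
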