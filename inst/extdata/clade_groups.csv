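clade,group
Mammalia,crown
Theria,crown
Eutheria,crown
Metatheria,crown
Multituberculata,crown
Eutriconodonta,crown
Symmetrodonta,crown
Dryolestida,crown
Monotremata,crown
Australosphenida,crown
Osteichthyes,stem
Synapsida,stem
Therapsida,stem
Cynodontia,stem
Probainognathia,stem
Tritylodontidae,stem
Tritheledontidae,stem
Traversodontidae,stem
Chiniquodontidae,stem
Dicynodontia,stem
Kannemeyeriiformes,stem
Mammaliaformes,stem
Morganucodonta,stem
Morganucodontidae,stem
Docodonta,stem
Docodontidae,stem
Sinoconodontidae,stem
Kuehneotheriidae,stem
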