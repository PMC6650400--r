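species,family,compound_name,smiles
host_kairomones,Brassicaceae,allyl isothiocyanate,C=CCN=C=S
host_kairomones,Brassicaceae,benzyl isothiocyanate,S=C=NCc1ccccc1
host_kairomones,Brassicaceae,3-(methylthio)propyl isothiocyanate,CSCCCN=C=S
host_kairomones,Brassicaceae,n-butyl isothiocyanate,CCCCN=C=S
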