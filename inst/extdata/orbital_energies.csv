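species,E_HOMO_kcal_mol,E_LUMO_kcal_mol
Ia,-183.24,-35.98
IIa,-180.38,-28.44
CH3SH,-183.240,-2.979
CH3S-,-173.453,77.998
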