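name,formula,pKa,role
GSH,C10H17N3O6S,8.83,thiol
NAC,C5H9NO3S,9.52,thiol
IIb,C19H18O,NA,chalcone
IIc,C19H18O2,NA,chalcone
Ib,C16H14O,NA,chalcone
Ic,C16H14O2,NA,chalcone
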