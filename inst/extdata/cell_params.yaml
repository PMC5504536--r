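G:
  Cm: 1.0
  gNa: 100.0
  gK: 80.0
  gL: 0.1
  ENa: 50.0
  EK: -100.0
  EL: -67.0
  Iext: 0.35
DI:
  Cm: 1.0
  gNa: 35.0
  gK: 9.0
  gL: 0.1
  ENa: 55.0
  EK: -90.0
  EL: -65.0
  Iext: 0.35
  phi: 5.0
mossy:
  Cm: 3.0
  gNa: 30.0
  gKdr: 15.0
  gCa: 7.0
  gKC: 15.0
  gKahp: 0.4
  gLs: 0.15
  gLd: 0.15
  gc: 2.1
  p: 0.5
  ENa: 60.0
  EK: -75.0
  ECa: 80.0
  EL: -65.0
  Is: 1.05
  Id: 0.0
P:
  Cm: 1.0
  gNa: 35.0
  gK: 9.0
  gL: 0.05
  ENa: 55.0
  EK: -90.0
  EL: -70.0
  Iext: 1.225
  gM: 1.0
  gNaP: 0.08
  gA: 1.6
I:
  Cm: 1.0
  gNa: 35.0
  gK: 9.0
  gL: 0.1
  ENa: 55.0
  EK: -90.0
  EL: -65.0
  Iext: 0.35
  phi: 5.0
O:
  Cm: 1.0
  gNa: 100.0
  gK: 80.0
  gL: 0.15
  ENa: 50.0
  EK: -100.0
  EL: -67.0
  Iext: 0.35
  gh: 0.1
  Eh: -32.9
  gM: 0.7
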