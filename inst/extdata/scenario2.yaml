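tool: trigame
version: 0.1.0
params:
  Cm: 6.0
  Ct: 2.0
  Cp: 10.0
  Ci: 0.5
  Wm: 9.0
  Wt: 7.0
  Gf: 6.0
  Gs: 5.0
  Er: 2.0
  Oc: 1.5
  Eg: 7.0
  Cr: 1.0
  Gg: 2.0
  Pg: 1.0
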