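# Named sequence-parameter presets: the standard 200 mm FOV,
# TR/TE 2200/30 ms protocol pair at grey-matter T2* (3 T).
epi64:
  scheme: EPI
  matrixPE: 64
  fovMM: 200
  teMS: 30
  trMS: 2200
  echoSpacingMS: 0.510
  keyholeFraction: 1.0
  nInterleaves: 1
  t2starMS: 66
epik96:
  scheme: EPIK
  matrixPE: 96
  fovMM: 200
  teMS: 30
  trMS: 2200
  echoSpacingMS: 0.890
  keyholeFraction: 0.25
  nInterleaves: 3
  t2starMS: 66
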