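# Example label (SmPC) expectedness registry: drug code -> expected PTs.
expected:
  L04AA27:
    - "Lymphopenia"
    - "Bradycardia"
  L04AA23:
    - "Progressive multifocal leukoencephalopathy"
    - "Headache"
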