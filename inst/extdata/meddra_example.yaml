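# Example reaction dictionary: PT -> SOC map plus synonym groups folding
# alias terms of the same clinical condition into one canonical PT.
pt_to_soc:
  "ALT increased": "Investigations"
  "Hypertransaminasaemia": "Hepatobiliary disorders"
  "Lymphopenia": "Blood and lymphatic system disorders"
  "Pyrexia": "General disorders and administration site conditions"
  "Abortion": "Pregnancy, puerperium and perinatal conditions"
synonym_groups:
  "SGPT raised": "ALT increased"
  "Fever": "Pyrexia"
  "Miscarriage": "Abortion"
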