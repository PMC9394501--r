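# CAD classification code lists. Ranges such as "I21-I23" are expanded at
# load time; codes are matched by prefix with dots removed, so "I21" covers
# every I21.x subcode. Medication entries are matched case-insensitively as
# substrings of free-text medication names.
mi_icd9: ["4109", "4129"]
mi_icd10: ["I21-I23", "I25.2"]
pci_opcs: ["K49", "K50", "K75"]
cabg_opcs: ["K40-K46"]
death_icd10: ["I20", "I21", "I24", "I25.1", "I25.2", "I25.5", "I25.8", "I25.9"]
angina_icd9: ["4139"]
angina_icd10: ["I20.0", "I20.1", "I20.8", "I20.9"]
exclusion_medications:
  - aspirin
  - glyceryl trinitrate
  - isosorbide mononitrate
  - isosorbide dinitrate
  - nicorandil
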