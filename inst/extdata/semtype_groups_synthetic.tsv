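semantic_type	semantic_group
Pharmacologic Substance	Chemicals and Drugs
Disease or Syndrome	Disorders
Gene or Genome	Genes and Molecular Sequences
Body Part, Organ, or Organ Component	Anatomy
Cell Function	Physiology
Organic Chemical	Chemicals and Drugs
Pathologic Function	Disorders
Finding	Disorders
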