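subject_semtype	predicate	object_semtype
Pharmacologic Substance	causes	Disease or Syndrome
Gene or Genome	causes	Disease or Syndrome
Pharmacologic Substance	treats	Disease or Syndrome
Pharmacologic Substance	inhibits	Cell Function
Pharmacologic Substance	inhibits	Gene or Genome
Pharmacologic Substance	stimulates	Cell Function
Pharmacologic Substance	prevents	Disease or Syndrome
Gene or Genome	predisposes	Disease or Syndrome
Body Part, Organ, or Organ Component	location_of	Disease or Syndrome
Disease or Syndrome	part_of	Body Part, Organ, or Organ Component
Pharmacologic Substance	interacts_with	Gene or Genome
Gene or Genome	interacts_with	Pharmacologic Substance
Disease or Syndrome	isa	Disease or Syndrome
Gene or Genome	associated_with	Disease or Syndrome
Disease or Syndrome	associated_with	Gene or Genome
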