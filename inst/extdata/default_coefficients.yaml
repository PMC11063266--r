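# Default risk coefficients (dimensionless), one per tissue class.
# Ordering follows qualitative severity: brainstem retraction carries
# respiratory/circulatory risk (highest); artery and cranial-nerve injury
# cause ischemia/bleeding and nerve deficits; venous injury causes
# troublesome bleeding; cerebellar retraction and bone drilling rank lower.
# Free operative space carries no injury risk by definition.
space: 0
bone: 1
cerebellum: 2
brainstem: 5
artery: 4
vein: 3
cranial_nerve: 4
other: 1
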