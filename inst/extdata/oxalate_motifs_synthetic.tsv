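# SYNTHETIC placeholder oxalate-binding motif set (PROSITE syntax).
# These patterns are lysine/arginine-centric stand-ins shipped so the pipeline
# runs end-to-end without external resources; they are NOT the published
# OxaBIND motif definitions. Replace this file with the published motif set
# for any real analysis. Every pipeline output records the motif-file
# checksum so the substitution is traceable.
oxm1	[KR]-x(2)-K-x-[KR]
oxm2	K-[ST]-x(1,2)-R
oxm3	R-G-[DE]-x-K
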