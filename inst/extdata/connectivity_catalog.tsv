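# built-in disulfide connectivity catalog (name, n_cys, ordinal pairs)
DEF8	8	1-8,2-5,3-6,4-7
TEN_A	10	1-10,2-6,3-7,4-9,5-8
TEN_B	10	1-9,2-10,3-6,4-7,5-8
TEN_C	10	1-10,2-5,3-7,4-8,6-9
EIGHT_ALT	8	1-4,2-6,3-7,5-8
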