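isolate,B.subtilis,MRSA,E.coli,C.albicans
MS.REE.1,Active,Active,Inactive,Inactive
MS.REE.3,Active,Inactive,Active,Inactive
MS.REE.4,Active,Active,Inactive,Inactive
MS.REE.6,Active,Inactive,Active,Inactive
MS.REE.9,Active,Inactive,Inactive,Inactive
MS.REE.10,Active,Active,Active,Inactive
MS.REE.12,Active,Inactive,Inactive,Inactive
MS.REE.13,Active,Active,Active,Inactive
MS.REE.14,Active,Inactive,Active,Inactive
MS.REE.16,Active,Inactive,Active,Inactive
MS.REE.17,Active,Inactive,Inactive,Inactive
MS.REE.18,Active,Inactive,Inactive,Inactive
MS.REE.19,Active,Inactive,Active,Inactive
MS.REE.22,Active,Active,Active,Inactive
MS.REE.24,Active,Inactive,Inactive,Inactive
MS.REE.25,Active,Active,Active,Inactive
MS.REE.26,Active,Active,Active,Inactive
MS.REE.27,Active,Active,Inactive,Inactive
MS.REE.28,Active,Active,Inactive,Inactive
MS.REE.29,Active,Inactive,Active,Inactive
MS.REE.32,Active,Inactive,Inactive,Inactive
MS.REE.33,Active,Inactive,Inactive,Inactive
MS.REE.34,Active,Inactive,Inactive,Inactive
MS.REE.36,Active,Inactive,Active,Inactive
MS.REE.46,Active,Inactive,Inactive,Inactive
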