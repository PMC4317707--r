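locus_id,rs_id,p_del,ho,n
HLD6,rs1610905,0.4574,0.4843,223
HLD39,rs17878444,0.8475,0.2511,223
HLD40,rs2307956,0.3767,0.5022,223
HLD45,rs2307959,0.3677,0.4484,223
HLD48,rs28369942,0.5919,0.5022,223
HLD56,rs2308292,0.4013,0.4529,223
HLD58,rs1610937,0.6996,0.3946,223
HLD64,rs1610935,0.2354,0.3363,223
HLD67,rs1305056,0.2848,0.4350,223
HLD70,rs2307652,0.3834,0.4350,223
HLD77,rs1611048,0.4843,0.5022,223
HLD81,rs17879936,0.1570,0.2422,223
HLD83,rs2308072,0.5942,0.4798,223
HLD84,rs3081400,0.1973,0.2780,223
HLD88,rs8190570,0.4215,0.4574,223
HLD92,rs17174476,0.5179,0.5247,223
HLD93,rs2307570,0.3789,0.4978,223
HLD97,rs17238892,0.6256,0.4081,223
HLD99,rs2308163,0.1570,0.2242,223
HLD101,rs2307433,0.5112,0.4843,223
HLD111,rs1305047,0.8767,0.2287,223
HLD114,rs2307581,0.6794,0.4439,223
HLD118,rs16438,0.0852,0.1704,223
HLD122,rs8178524,0.7265,0.3767,223
HLD124,rs6481,0.4126,0.5112,223
HLD125,rs16388,0.5919,0.4753,223
HLD128,rs2307924,0.6390,0.4260,223
HLD131,rs1611001,0.6861,0.3946,223
HLD133,rs2067235,0.5942,0.4709,223
HLD136,rs16363,0.4574,0.5202,223
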