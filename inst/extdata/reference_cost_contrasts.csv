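drug,group,n,pre_ip,pre_op,pre_rx,pre_total,inc_ip,inc_op,inc_rx,inc_total
ADL,persistent,4,0,263,97,360,0,2460,-27,2433
ADL,non_persistent,10,0,81,286,367,204,946,471,1621
ADL,difference,14,0,-182,189,7,204,-1514,498,-812
IFX,persistent,6,603,398,61,1062,-174,2446,-26,2246
IFX,non_persistent,13,249,198,401,848,1005,1756,-153,2608
IFX,difference,19,-354,-200,340,-214,1179,-690,-127,362
UST,persistent,23,201,211,186,597,-98,2380,-71,2211
UST,non_persistent,7,36,232,353,621,414,2021,-180,2254
UST,difference,30,-165,21,167,24,512,-359,-109,43
subtotal,persistent,33,250,251,152,653,-100,2402,-57,2244
subtotal,non_persistent,31,122,166,341,629,577,1499,50,2126
subtotal,difference,64,-128,-85,189,-24,677,-903,107,-118
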