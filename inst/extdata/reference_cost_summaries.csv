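population,group,drug,n,pre_ip,pre_op,pre_rx,pre_total,inc_ip,inc_op,inc_rx,inc_total
total,all,ADL,18,18,513,229,760,95,1077,366,1538
total,all,IFX,20,343,301,306,950,601,1958,-130,2429
total,all,UST,37,254,425,221,900,-37,2011,-109,1865
total,all,subtotal,77,235,405,246,886,156,1754,-2,1907
naive,all,ADL,14,0,133,232,365,146,1379,328,1853
naive,all,IFX,19,361,261,294,916,633,1974,-113,2494
naive,all,UST,30,162,216,225,603,21,2296,-96,2221
naive,all,subtotal,64,188,210,244,641,228,1965,-5,2187
total,persistent,ADL,6,55,876,161,1092,-55,1365,295,1606
total,persistent,IFX,6,603,398,61,1062,-174,2446,-26,2246
total,persistent,UST,29,315,418,192,925,-147,2114,-91,1875
total,persistent,subtotal,42,340,473,175,988,-140,2054,-30,1883
naive,persistent,ADL,4,0,263,97,360,0,2461,-27,2433
naive,persistent,IFX,6,603,398,61,1062,-174,2446,-26,2246
naive,persistent,UST,23,201,211,186,597,-98,2380,-71,2211
naive,persistent,subtotal,33,250,251,152,653,-100,2402,-57,2244
total,non_persistent,ADL,12,0,332,263,595,170,932,402,1504
total,non_persistent,IFX,14,231,259,412,902,933,1749,-175,2507
total,non_persistent,UST,8,32,448,328,808,362,1638,-172,1828
total,non_persistent,subtotal,35,108,324,330,762,511,1395,31,1937
naive,non_persistent,ADL,10,0,81,286,367,204,946,470,1620
naive,non_persistent,IFX,13,249,198,401,848,1005,1756,-153,2608
naive,non_persistent,UST,7,36,232,353,621,414,2021,-181,2254
naive,non_persistent,subtotal,31,122,166,341,629,577,1499,50,2126
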