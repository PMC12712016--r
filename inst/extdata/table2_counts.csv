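case_id,injection_label,injected_area,region,total,ipsi,contra,homotopic,pct_contra_printed,pct_homotopic_printed
64FB,46d (r),46d,prefrontal,15919,11804,4115,2374,25.8,57.7
60FB,46d (i),46d,prefrontal,27710,24904,2806,1380,10.1,49.2
58FB,46d (c),46d,prefrontal,21139,18676,2463,1272,11.7,51.6
48FB,12r (r),12r,prefrontal,15157,11244,3913,427,25.8,10.9
48DY,12r (r),12r,prefrontal,12629,10327,2302,460,18.2,20.0
52FB,46v (i),46v,prefrontal,15240,13429,1811,667,11.9,36.8
52DY,46v (i),46v,prefrontal,12600,10582,2018,1594,16.0,79.0
59FB,12r (i),12r,prefrontal,15504,12311,3193,2076,20.6,65.0
30FB,45B,45B,prefrontal,25591,23951,1640,799,6.4,48.7
56FB,GrFO,GrFO,frontal_opercular,27857,22604,5253,1502,18.9,28.6
56DY,PrCO,PrCO,frontal_opercular,11028,10256,772,162,7.0,21.0
42FB,DO,DO,frontal_opercular,19703,18765,938,257,4.8,27.4
30DY,F5a,F5a,premotor,5729,5289,440,337,7.7,76.6
42DY,F5a,F5a,premotor,5346,4670,676,302,12.6,44.7
30CTBg,F5p,F5p,premotor,23019,20993,2026,551,8.8,27.2
18FB,F4,F4,premotor,22695,18715,3980,1255,17.5,31.5
12DY,F2,F2,premotor,16781,14702,2079,1767,12.4,85.0
11FB,F2,F2,premotor,13166,11040,2126,1075,16.1,50.6
13FB,F7,F7,premotor,23338,19440,3898,1864,16.7,47.8
11DY,F7,F7,premotor,15211,12462,2749,1376,18.1,50.1
65FB,F3,F3,premotor,7353,6291,1062,249,14.4,23.4
65DY,F6,F6,premotor,18596,16003,2593,556,13.9,21.4
13TB,F1,F1,F1,2079,2030,49,3,2.4,6.1
62FR,F1,F1,F1,33812,33566,246,156,0.7,63.4
27DY,Opt,Opt,parietal,19080,17939,1141,436,6.0,38.2
27TB,Opt,Opt,parietal,7755,7128,627,358,8.1,57.1
29TB,PG,PG,parietal,8580,7456,1124,895,13.1,79.6
29FB,PFG,PFG,parietal,17073,16281,792,271,4.6,34.2
29DY,PF,PF,parietal,31273,30900,373,175,1.2,46.9
27FB,PF,PF,parietal,12758,12645,113,69,0.9,61.1
74FB,AIP,AIP,parietal,6726,6106,620,266,9.2,42.9
74DY,AIP,AIP,parietal,16366,13900,2466,639,15.1,25.9
73DY,MIP,MIP,parietal,64758,61135,3623,974,5.6,26.9
72FB,MIP,MIP,parietal,23839,21927,1912,432,8.0,22.6
72DY,PEip,PEip,parietal,66017,62312,3705,1094,5.6,29.5
73FB,PEip,PEip,parietal,23528,20556,2972,458,12.6,15.4
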