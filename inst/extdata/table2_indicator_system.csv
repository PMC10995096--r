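id,abbrev,name,layer,class,weight_percent,polarity
1,U,Urbanization,SEI,,0.907,benefit
2,PS,Population scale,SEI,,2.151,benefit
3,PGR,Population growth ratio,SEI,,0.601,benefit
4,GDP,Gross domestic product,SEI,,2.222,benefit
5,GDPGR,GDP growth ratio,SEI,,0.622,benefit
6,BD,Building density,SEI,,0.693,benefit
7,RND,Road network density,SEI,,1.369,benefit
8,PN,Park number,SEI,,1.102,benefit
9,SD,Sunshine duration,EEI,,2.471,benefit
10,AA,Arable area,EEI,,1.547,benefit
11,WA,Water area,EEI,,2.293,benefit
12,TWR,Total water resources,EEI,,1.511,benefit
13,WRPC,Water resources per capita,EEI,,2.187,benefit
14,FCR,Forest cover ratio,EEI,,1.511,benefit
15,GRBA,Greening rate in built-up area,EEI,,0.764,benefit
16,GSPC,Green space per capita,EEI,,1.689,benefit
17,CPN,City park number,EEI,,2.634,benefit
18,NP,Number of plaques,LPCI,vegetation,4.494,benefit
19,DP,Density of plaques,LPCI,vegetation,2.841,benefit
20,AREA_MN,Average plaque size,LPCI,vegetation,1.188,benefit
21,LPI,Largest plaque index,LPCI,vegetation,0.981,benefit
22,LSI,Landscape shape index,LPCI,vegetation,3.771,benefit
23,AI,Plaque aggregation,LPCI,vegetation,3.461,benefit
24,NP,Number of plaques,LPCI,water,3.564,benefit
25,DP,Density of plaques,LPCI,water,0.465,benefit
26,AREA_MN,Average plaque size,LPCI,water,2.324,benefit
27,LPI,Largest plaque index,LPCI,water,0.671,benefit
28,LSI,Landscape shape index,LPCI,water,2.738,benefit
29,AI,Plaque aggregation,LPCI,water,3.151,benefit
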