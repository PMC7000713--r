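"mass_kg","density_per_km2"
10,2.3968564871583
14.3844988828766,1.82482397680413
20.6913808111479,1.38931244492959
29.7635144163132,1.05773986651394
42.8133239871939,0.805300225515237
61.5848211066026,0.613107696651562
88.5866790410084,0.466783735783607
127.427498570314,0.35538137456449
183.298071083244,0.270566242363455
263.665089873036,0.205993045067125
379.269019073225,0.156830853122562
545.559478116852,0.119401684086644
784.759970351462,0.0909053408743825
1128.83789168469,0.0692099199663805
1623.77673918872,0.052692316817467
2335.72146909012,0.0401167961607385
3359.81828628379,0.0305425426590611
4832.93023857176,0.0232532754695282
6951.92796177561,0.0177036609589984
10000,0.0134785145327968
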