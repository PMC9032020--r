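label_id,name,hemisphere,area
1001,ctx-lh-bankssts,lh,temporal
1002,ctx-lh-caudalanteriorcingulate,lh,cingulate
1003,ctx-lh-caudalmiddlefrontal,lh,frontal
1004,ctx-lh-corpuscallosum,lh,unknown
1005,ctx-lh-cuneus,lh,occipital
1006,ctx-lh-entorhinal,lh,temporal
1007,ctx-lh-fusiform,lh,temporal
1008,ctx-lh-inferiorparietal,lh,parietal
1009,ctx-lh-inferiortemporal,lh,temporal
1010,ctx-lh-isthmuscingulate,lh,cingulate
1011,ctx-lh-lateraloccipital,lh,occipital
1012,ctx-lh-lateralorbitofrontal,lh,frontal
1013,ctx-lh-lingual,lh,occipital
1014,ctx-lh-medialorbitofrontal,lh,frontal
1015,ctx-lh-middletemporal,lh,temporal
1016,ctx-lh-parahippocampal,lh,temporal
1017,ctx-lh-paracentral,lh,frontal
1018,ctx-lh-parsopercularis,lh,frontal
1019,ctx-lh-parsorbitalis,lh,frontal
1020,ctx-lh-parstriangularis,lh,frontal
1021,ctx-lh-pericalcarine,lh,occipital
1022,ctx-lh-postcentral,lh,parietal
1023,ctx-lh-posteriorcingulate,lh,cingulate
1024,ctx-lh-precentral,lh,frontal
1025,ctx-lh-precuneus,lh,parietal
1026,ctx-lh-rostralanteriorcingulate,lh,cingulate
1027,ctx-lh-rostralmiddlefrontal,lh,frontal
1028,ctx-lh-superiorfrontal,lh,frontal
1029,ctx-lh-superiorparietal,lh,parietal
1030,ctx-lh-superiortemporal,lh,temporal
1031,ctx-lh-supramarginal,lh,parietal
1032,ctx-lh-frontalpole,lh,frontal
1033,ctx-lh-temporalpole,lh,temporal
1034,ctx-lh-transversetemporal,lh,temporal
1035,ctx-lh-insula,lh,unknown
2001,ctx-rh-bankssts,rh,temporal
2002,ctx-rh-caudalanteriorcingulate,rh,cingulate
2003,ctx-rh-caudalmiddlefrontal,rh,frontal
2004,ctx-rh-corpuscallosum,rh,unknown
2005,ctx-rh-cuneus,rh,occipital
2006,ctx-rh-entorhinal,rh,temporal
2007,ctx-rh-fusiform,rh,temporal
2008,ctx-rh-inferiorparietal,rh,parietal
2009,ctx-rh-inferiortemporal,rh,temporal
2010,ctx-rh-isthmuscingulate,rh,cingulate
2011,ctx-rh-lateraloccipital,rh,occipital
2012,ctx-rh-lateralorbitofrontal,rh,frontal
2013,ctx-rh-lingual,rh,occipital
2014,ctx-rh-medialorbitofrontal,rh,frontal
2015,ctx-rh-middletemporal,rh,temporal
2016,ctx-rh-parahippocampal,rh,temporal
2017,ctx-rh-paracentral,rh,frontal
2018,ctx-rh-parsopercularis,rh,frontal
2019,ctx-rh-parsorbitalis,rh,frontal
2020,ctx-rh-parstriangularis,rh,frontal
2021,ctx-rh-pericalcarine,rh,occipital
2022,ctx-rh-postcentral,rh,parietal
2023,ctx-rh-posteriorcingulate,rh,cingulate
2024,ctx-rh-precentral,rh,frontal
2025,ctx-rh-precuneus,rh,parietal
2026,ctx-rh-rostralanteriorcingulate,rh,cingulate
2027,ctx-rh-rostralmiddlefrontal,rh,frontal
2028,ctx-rh-superiorfrontal,rh,frontal
2029,ctx-rh-superiorparietal,rh,parietal
2030,ctx-rh-superiortemporal,rh,temporal
2031,ctx-rh-supramarginal,rh,parietal
2032,ctx-rh-frontalpole,rh,frontal
2033,ctx-rh-temporalpole,rh,temporal
2034,ctx-rh-transversetemporal,rh,temporal
2035,ctx-rh-insula,rh,unknown
17,Left-Hippocampus,lh,hippocampus
18,Left-Amygdala,lh,amygdala
53,Right-Hippocampus,rh,hippocampus
54,Right-Amygdala,rh,amygdala
4,Left-Lateral-Ventricle,lh,unknown
5,Left-Inf-Lat-Vent,lh,unknown
43,Right-Lateral-Ventricle,rh,unknown
44,Right-Inf-Lat-Vent,rh,unknown
14,3rd-Ventricle,,unknown
15,4th-Ventricle,,unknown
24,CSF,,unknown
0,Unknown,,unknown
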