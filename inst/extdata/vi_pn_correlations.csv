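feature,jointing_booting,heading_flowering,ripening
NIRv,0.3262,0.2034,-0.0903
CIgreen,0.3893,0.3490,0.1693
CIrededge,0.1938,0.1046,0.0649
CVI,0.3396,0.1155,0.1605
DVI,0.3186,0.1737,-0.1083
EVI,0.2803,0.1333,-0.0949
GI,-0.1549,-0.0196,0.0137
GNDVI,-0.1473,0.1699,-0.0531
MCARI,-0.0091,-0.0642,-0.095
MNVI,0.3342,0.2119,-0.0798
MSAVI,0.3281,0.2194,-0.0820
MSR,0.3157,0.1905,0.0926
MTCI,0.1369,0.0886,0.0742
MTVI,0.1419,0.1113,-0.0846
NDVI,0.3178,0.3166,0.0370
NLI,0.3386,0.2661,-0.0056
OSAVI,0.3330,0.2622,-0.0487
RDVI,0.3342,0.2259,-0.0746
RVI1,0.3136,0.1038,0.1223
RVI2,0.3893,0.3490,0.1693
SIPI,0.3258,0.3381,0.0648
TCARI,-0.2753,-0.3014,-0.2131
TVI,-0.1262,-0.2094,-0.1258
VARI,-0.0984,0.0632,-0.0685
VDVI,-0.1881,0.2746,-0.0680
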