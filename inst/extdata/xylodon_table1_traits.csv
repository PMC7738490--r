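specimen,species,country,basidia_L,basidia_W,spore_L,spore_W,spore_Q
K 56442 (Holotype),Xylodon australis,Australia,29.8,5.1,7.2,5.1,1.41
CANB 569566,Xylodon australis,Australia,28.58,4.75,7.3,4.6,1.59
CANB 569567,Xylodon australis,Australia,32,4.83,6.8,4.4,1.55
CANB 569568,Xylodon australis,Australia,28,4.3,6.3,4.2,1.50
CANB 569570,Xylodon australis,Australia,26.5,4.75,6.7,4.3,1.56
CANB 569572,Xylodon australis,Australia,30,4.7,7.3,4.4,1.66
CANB 751963,Xylodon australis,Australia,28.7,4.97,6.4,4.2,1.52
CANB 752080,Xylodon australis,Australia,29.65,4.5,7,4,1.75
CANB 752088,Xylodon australis,Australia,28.3,4.7,6.7,4.1,1.63
CANB 869100,Xylodon australis,Australia,28.85,5,6.5,4,1.63
CANB 869124,Xylodon australis,Australia,30.3,5,6.3,4.1,1.54
PDD 23689,Xylodon australis,New Zealand,28.5,4,7.1,4.6,1.54
PDD 23691,Xylodon australis,New Zealand,30.56,5,6.8,5.2,1.31
PDD 23692,Xylodon australis,New Zealand,29.75,4.85,6.85,5.2,1.32
PDD 23693,Xylodon australis,New Zealand,31,4.75,6.8,4.9,1.39
PDD 23694,Xylodon australis,New Zealand,29.8,4.5,6.6,4.6,1.43
PDD 23696,Xylodon australis,New Zealand,30.45,4.67,6.1,4,1.53
PDD 23698,Xylodon australis,New Zealand,30.66,4.33,6.6,4.5,1.47
PDD 23699,Xylodon australis,New Zealand,26.33,4.66,6.7,4.4,1.52
PDD 23703,Xylodon australis,New Zealand,25.83,4,6.9,5,1.38
PDD 23704,Xylodon australis,New Zealand,29.5,4,6.4,4.7,1.36
PDD 23705,Xylodon australis,New Zealand,30.1,4.7,6.2,4.4,1.41
Wu 890714 (Isotype),Xylodon lenis,Taiwan,18.5,3.75,4.75,3.25,1.46
AG 730,Xylodon magallanesii,Argentina,22.65,4,5.6,3,1.87
AG 1548,Xylodon magallanesii,Argentina,23.75,4.62,6.1,2.9,2.10
AG 1872,Xylodon magallanesii,Argentina,23.22,4.35,6,3,2.00
MA-Fungi 90397 (Holotype),Xylodon magallanesii,Chile,24.5,4.75,5.6,2.87,1.95
MA-Fungi 90391,Xylodon magallanesii,Chile,21.4,4,6.4,3,2.13
MA-Fungi 90392,Xylodon magallanesii,Chile,23,4,5.8,3,1.93
MA-Fungi 90393,Xylodon magallanesii,Chile,22.5,4.5,6,3,2.00
MA-Fungi 91815,Xylodon magallanesii,Chile,22.5,4.25,5.54,2.45,2.26
MA-Fungi 91816,Xylodon magallanesii,Chile,27,4,5.1,2.65,1.92
MA-Fungi 91817,Xylodon magallanesii,Chile,23.3,3.83,5.95,2.77,2.14
MA-Fungi 91818,Xylodon magallanesii,Chile,NA,NA,5.17,2.50,2.06
MA-Fungi 91819,Xylodon magallanesii,Chile,24,4.16,5.6,2.45,2.28
MA-Fungi 91820,Xylodon magallanesii,Chile,NA,NA,NA,NA,NA
MA-Fungi 91821,Xylodon magallanesii,Chile,23,4.5,5.72,2.90,1.97
PDD 69093,Xylodon magallanesii,Argentina,21.85,4,6.3,3,2.10
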