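plane,modality,set,bone,x1,y1,x2,y2,area
transverse,CT,1,patella,0.398,0.252,NA,NA,0.0079
transverse,CT,1,femur,0.512,0.473,NA,NA,0.0775
transverse,CT,1,tibia,0.635,0.477,0.522,0.574,0.2154
transverse,CT,2,patella,0.428,0.25,NA,NA,0.0137
transverse,CT,2,femur,0.514,0.47,NA,NA,0.0821
transverse,CT,2,tibia,0.505,0.578,NA,NA,0.2157
transverse,CT,3,patella,0.443,0.254,NA,NA,0.0217
transverse,CT,3,femur,0.517,0.465,NA,NA,0.0901
transverse,CT,3,tibia,0.505,0.558,NA,NA,0.2087
transverse,CT,4,patella,0.436,0.256,NA,NA,0.0348
transverse,CT,4,femur,0.521,0.471,NA,NA,0.1094
transverse,CT,4,tibia,0.508,0.553,NA,NA,0.2054
transverse,CT,5,patella,0.436,0.258,NA,NA,0.0494
transverse,CT,5,femur,0.529,0.484,NA,NA,0.1353
transverse,CT,5,tibia,0.509,0.543,NA,NA,0.1997
transverse,CT,6,patella,0.453,0.271,NA,NA,0.0596
transverse,CT,6,femur,0.522,0.487,NA,NA,0.2298
transverse,CT,6,tibia,0.521,0.543,NA,NA,0.1675
transverse,CT,7,patella,0.478,0.285,NA,NA,0.0615
transverse,CT,7,femur,0.518,0.49,NA,NA,0.2343
transverse,CT,7,tibia,0.552,0.533,NA,NA,0.144
transverse,CT,8,patella,0.453,0.277,NA,NA,0.0598
transverse,CT,8,femur,0.518,0.478,NA,NA,0.2389
transverse,CT,8,tibia,0.514,0.555,NA,NA,0.1343
transverse,CT,9,patella,0.441,0.276,NA,NA,0.0521
transverse,CT,9,femur,0.519,0.451,NA,NA,0.2428
transverse,CT,9,tibia,0.517,0.584,NA,NA,0.1291
transverse,CT,10,patella,0.436,0.279,NA,NA,0.0387
transverse,CT,10,femur,0.535,0.496,NA,NA,0.2263
transverse,CT,10,tibia,0.517,0.605,NA,NA,0.1255
transverse,CT,11,patella,0.436,0.285,NA,NA,0.0103
transverse,CT,11,femur,0.633,0.469,0.518,0.568,0.0877
transverse,CT,11,tibia,0.517,0.613,NA,NA,0.115
sagittal,MR,1,patella,0,0,NA,NA,0
sagittal,MR,1,femur,0.526,0.441,NA,NA,0.0411
sagittal,MR,1,tibia,0.495,0.603,NA,NA,0.0174
sagittal,MR,2,patella,0,0,NA,NA,0
sagittal,MR,2,femur,0.514,0.424,NA,NA,0.0753
sagittal,MR,2,tibia,0.512,0.618,NA,NA,0.0271
sagittal,MR,3,patella,0.188,0.324,NA,NA,0.0011
sagittal,MR,3,femur,0.475,0.411,NA,NA,0.1064
sagittal,MR,3,tibia,0.494,0.651,NA,NA,0.0526
sagittal,MR,4,patella,0.234,0.398,NA,NA,0.0028
sagittal,MR,4,femur,0.468,0.385,NA,NA,0.1178
sagittal,MR,4,tibia,0.509,0.69,NA,NA,0.0786
sagittal,MR,5,patella,0.238,0.399,NA,NA,0.0125
sagittal,MR,5,femur,0.428,0.381,NA,NA,0.1114
sagittal,MR,5,tibia,0.492,0.71,NA,NA,0.1128
sagittal,MR,6,patella,0.243,0.393,NA,NA,0.0196
sagittal,MR,6,femur,0.422,0.229,NA,NA,0.0949
sagittal,MR,6,tibia,0.468,0.708,NA,NA,0.1084
sagittal,MR,7,patella,0.241,0.403,NA,NA,0.0169
sagittal,MR,7,femur,0.419,0.286,NA,NA,0.1006
sagittal,MR,7,tibia,0.467,0.702,NA,NA,0.0884
sagittal,MR,8,patella,0.245,0.411,NA,NA,0.0076
sagittal,MR,8,femur,0.446,0.318,NA,NA,0.1416
sagittal,MR,8,tibia,0.484,0.692,NA,NA,0.0796
sagittal,MR,9,patella,0.254,0.417,NA,NA,0.0032
sagittal,MR,9,femur,0.453,0.377,NA,NA,0.1195
sagittal,MR,9,tibia,0.477,0.665,NA,NA,0.0608
sagittal,MR,10,patella,0.3,0.383,NA,NA,1e-04
sagittal,MR,10,femur,0.477,0.42,NA,NA,0.0892
sagittal,MR,10,tibia,0.488,0.645,NA,NA,0.0345
sagittal,MR,11,patella,0,0,NA,NA,0
sagittal,MR,11,femur,0.498,0.421,NA,NA,0.0109
sagittal,MR,11,tibia,0.507,0.622,NA,NA,0.0233
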