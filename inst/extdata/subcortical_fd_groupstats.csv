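structure,side,median_scz,min_scz,max_scz,median_hc,min_hc,max_hc,u,p
Thalamus,L,2.423,2.398,2.436,2.428,2.416,2.437,86.5,0.005
Thalamus,R,2.402,2.364,2.421,2.405,2.396,2.418,132.5,0.163
Caudate,L,2.200,2.136,2.261,2.210,2.177,2.232,134.5,0.181
Caudate,R,2.216,2.034,2.266,2.190,2.107,2.257,134.5,0.181
Putamen,L,2.370,2.347,2.420,2.375,2.320,2.430,173.5,0.840
Putamen,R,2.269,2.245,2.307,2.273,2.237,2.311,135.5,0.191
Pallidum,L,2.146,2.061,2.373,2.121,2.078,2.200,127,0.123
Pallidum,R,2.160,2.067,2.215,2.117,1.927,2.184,110,0.040
Hippocampus,L,2.146,2.066,2.184,2.173,2.150,2.230,56,0.0005
Hippocampus,R,2.143,2.045,2.193,2.176,2.123,2.207,84.5,0.004
Amygdala,L,2.347,2.280,2.404,2.339,2.265,2.376,141.5,0.258
Amygdala,R,2.345,2.204,2.446,2.356,2.278,2.427,149.5,0.370
NucleusAccumbens,L,1.976,1.851,3.012,2.000,1.827,2.648,139.5,0.234
NucleusAccumbens,R,2.093,1.785,2.402,2.156,2.041,2.349,133,0.172
Brainstem,M,2.470,2.455,2.678,2.467,2.451,2.508,129.5,0.138
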