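level,band_lo_khz,band_hi_khz,mean_qi,sd_qi,mean_yin,sd_yin,mean_healthy,sd_healthy,p_value
1,4,8,1.303,0.346,1.266,0.346,1.490,0.374,0.011
2,4,6,1.356,0.356,1.304,0.358,1.567,0.357,0.005
2,6,8,1.428,0.312,1.410,0.289,1.632,0.220,0.002
3,3,4,1.104,0.266,1.131,0.306,1.256,0.296,0.035
3,4,5,1.359,0.364,1.319,0.406,1.582,0.362,0.005
3,5,6,1.406,0.334,1.412,0.339,1.636,0.332,0.003
3,6,7,1.541,0.292,1.524,0.313,1.755,0.251,0.001
3,7,8,1.600,0.266,1.544,0.279,1.703,0.269,0.044
4,0.5,1,1.240,0.220,1.276,0.289,1.397,0.293,0.005
4,1,1.5,1.284,0.263,1.334,0.310,1.434,0.324,0.029
4,1.5,2,1.238,0.307,1.246,0.352,1.431,0.303,0.021
4,2.5,3,1.346,0.290,1.392,0.342,1.544,0.287,0.009
4,3,3.5,1.317,0.277,1.359,0.325,1.472,0.306,0.048
4,3.5,4,1.418,0.348,1.444,0.355,1.661,0.351,0.002
4,4,4.5,1.459,0.373,1.452,0.406,1.733,0.358,0.001
4,4.5,5,1.476,0.351,1.481,0.385,1.670,0.386,0.014
4,5,5.5,1.482,0.337,1.532,0.346,1.712,0.313,0.004
4,5.5,6,1.582,0.284,1.578,0.329,1.815,0.283,0.001
4,6,6.5,1.596,0.296,1.576,0.335,1.782,0.306,0.005
4,6.5,7,1.610,0.274,1.608,0.321,1.824,0.224,0.002
4,7,7.5,1.793,0.232,1.759,0.242,1.914,0.219,0.015
5,0,0.25,1.487,0.304,1.459,0.275,1.269,0.386,0.020
5,0.5,0.75,1.446,0.242,1.457,0.250,1.601,0.238,0.008
5,0.75,1,1.410,0.273,1.475,0.326,1.612,0.321,0.004
5,1,1.25,1.380,0.295,1.436,0.327,1.584,0.323,0.005
5,1.25,1.5,1.423,0.301,1.429,0.344,1.603,0.374,0.025
5,1.5,1.75,1.459,0.323,1.433,0.378,1.635,0.322,0.041
5,2.5,2.75,1.470,0.302,1.459,0.366,1.647,0.328,0.020
5,2.75,3,1.448,0.306,1.501,0.358,1.638,0.286,0.015
5,3.25,3.5,1.489,0.287,1.508,0.323,1.652,0.315,0.025
5,3.5,3.75,1.587,0.335,1.608,0.342,1.784,0.336,0.008
5,3.75,4,1.611,0.383,1.613,0.367,1.823,0.354,0.007
5,4,4.25,1.622,0.379,1.607,0.371,1.832,0.387,0.005
5,4.25,4.5,1.617,0.349,1.605,0.369,1.847,0.333,0.002
5,4.5,4.75,1.624,0.321,1.594,0.381,1.791,0.346,0.016
5,4.75,5,1.588,0.337,1.588,0.377,1.759,0.359,0.028
5,5,5.25,1.567,0.346,1.614,0.353,1.761,0.332,0.008
5,5.25,5.5,1.631,0.300,1.642,0.355,1.897,0.216,0.000
5,5.5,5.75,1.703,0.277,1.700,0.315,1.903,0.254,0.002
5,5.75,6,1.760,0.255,1.784,0.266,1.924,0.205,0.005
5,6,6.25,1.767,0.268,1.767,0.278,1.902,0.245,0.020
5,6.25,6.5,1.712,0.272,1.702,0.336,1.884,0.257,0.006
5,6.5,6.75,1.706,0.287,1.690,0.349,1.891,0.242,0.005
5,6.75,7,1.783,0.252,1.776,0.305,1.945,0.223,0.007
5,7,7.25,1.863,0.230,1.848,0.251,1.991,0.193,0.018
5,7.25,7.5,1.923,0.223,1.896,0.249,2.040,0.161,0.010
5,7.5,7.75,2.026,0.164,1.997,0.149,2.034,0.251,0.037
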