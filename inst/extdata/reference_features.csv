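# Published simulated feature values of the four best-fit reference models
# (columns FF1-FF4), for cross-checking reproduced feature tables.
# Values in parentheses in the original publication (features not included
# in that model's fitness function) are listed plainly here.
feature,amplitude_pA,frequency_Hz,FF1,FF2,FF3,FF4
burst,6,0.58,36.77,37.66,35.73,35.19
burst,6,2.12,47.36,46.29,47.52,46.15
burst,6,4.04,51.78,52.82,51.81,50.74
burst,6,5.96,55.22,54.32,52.36,53.28
burst,6,8.08,55.04,53.93,55.25,54.74
burst,6,10.19,50.51,57.97,50.48,55.25
burst,8,0.58,45.62,42.63,45.78,42.68
burst,8,2.12,55.42,55.75,56.70,53.97
burst,8,4.04,59.03,61.01,59.84,60.39
burst,8,5.96,63.16,65.57,63.83,63.07
burst,8,8.08,64.43,66.23,64.94,64.52
burst,8,10.19,69.44,68.94,69.93,67.57
burst,8,12.31,66.23,58.62,66.94,66.01
burst,8,14.23,49.30,71.43,50.02,51.74
mean_frequency,10,,1,30,2,19
mean_frequency,16,,35,49,35,45
mean_frequency,22,,72,67,73,66
latency,10,,45.8,9.9,36.10,14.90
latency,16,,12.8,6.4,12.40,9.00
latency,22,,8.5,5.0,8.40,6.70
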