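# Experimental feature targets for cerebellar granule cell model fitting:
# burst frequencies under sinusoidal stimulation (12-pA offset) from in
# vitro patch-clamp recordings, and mean firing frequency / first-spike
# latency under 1-s step currents. frequency_Hz is the sinusoidal
# stimulation frequency (empty for step protocols).
feature,amplitude_pA,frequency_Hz,value,unit
burst,6,0.58,41.43,Hz
burst,6,2.12,49.29,Hz
burst,6,4.04,54.00,Hz
burst,6,5.96,59.29,Hz
burst,6,8.08,55.00,Hz
burst,6,10.19,45.71,Hz
burst,8,0.58,45.00,Hz
burst,8,2.12,55.71,Hz
burst,8,4.04,60.00,Hz
burst,8,5.96,65.71,Hz
burst,8,8.08,66.43,Hz
burst,8,10.19,64.29,Hz
burst,8,12.31,58.57,Hz
burst,8,14.23,50.00,Hz
mean_frequency,10,,30,Hz
mean_frequency,16,,45,Hz
mean_frequency,22,,60,Hz
latency,10,,31.90,ms
latency,16,,19.00,ms
latency,22,,14.65,ms
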