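# Published best-fit AdEx parameter sets for the cerebellar granule cell,
# one column per fitness-function variant (FF1: bursts only; FF2: bursts +
# mean frequency; FF3: bursts + first-spike latency; FF4: all three).
# Units: C_m pF; Delta_T, E_L, V_peak, V_r, V_T mV; a, g_L nS; b pA; tau_w ms.
parameter,FF1,FF2,FF3,FF4
C_m,3.10,4.21,3.36,2.80
Delta_T,5.42,1.09,7.01,22.07
E_L,-64.06,-51.42,-59.92,-58.00
V_peak,-13.49,6.80,-12.24,-17.56
V_r,-70.28,-73.66,-64.86,-71.31
V_T,-40.59,-38.00,-40.31,-24.01
a,0.26,0.36,0.36,0.23
b,0.19,0.65,0.15,0.37
g_L,0.49,0.17,0.67,0.25
tau_w,327.25,338.75,365.41,619.07
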