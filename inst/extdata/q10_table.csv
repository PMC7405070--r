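property,mean_q10,sem
current threshold (ct: pA),1.67,0.24
RMP (mV),1.04,0.02
Rm (MΩ),0.81,0.09
2xct: AP rise/AP half-width,7.75,0.93
ct: AP rise/AP half-width,7.33,0.73
Max AP: AP rise/AP half-width,6.96,1.01
2xct: adaptation (Hz),3.28,0.68
2xct: max AP decay (mV/ms),3.27,0.22
Max AP: max AP decay (mV/ms),3.15,0.30
ct: max AP decay (mV/ms),2.92,0.18
2xct: max AP rise (mV/ms),1.80,0.14
ct: max AP rise (mV/ms),1.75,0.10
Max AP: max AP rise (mV/ms),1.67,0.16
ct: AP rise/decay ratio,0.62,0.04
2xct: AP rise/decay ratio,0.56,0.03
Max AP: AP rise/decay ratio,0.54,0.03
Max AP: AP half-width (ms),0.27,0.02
ct: AP half-width (ms),0.26,0.02
2xct: AP half-width (ms),0.26,0.02
Max AP: # AP,5.26,1.51
Initial adaptation change (2) (Hz/pA),5.11,0.99
Max AP: change of instant frequency from 1st to 2nd AP pair (Hz),4.68,1.63
2xct: initial instant frequency (Hz),4.60,1.07
2xct: change of instant frequency from 1st to 2nd AP pair (Hz),4.09,0.75
Max AP: adaptation (Hz),4.08,1.32
2xct: # AP,4.05,0.74
Max initial adaptation change (Hz/pA),3.29,0.51
Max AP: initial instant frequency (Hz),3.28,0.55
2xct: change of ISI duration from 1st to 2nd AP (ms),1.52,0.44
2xct: SD of first 2 ISI (ms),1.42,0.42
Max AP: ISI ratio,1.21,0.25
2xct: ISI ratio,1.15,0.15
Max adaptation change relative to ct,1.12,0.14
Max adaptation change relative to ct (2),1.04,0.15
2xct: mean of first 2 ISI (ms),0.61,0.15
Max AP: change of ISI duration from 1st to 2nd AP (ms),0.53,0.30
Max AP: mean of first 2 ISI (ms),0.41,0.10
Max AP: SD of first 2 ISI (ms),0.20,0.09
2xct: AP thresh/AP ampl,1.72,0.11
ct: AP threshold/AP amp.,1.69,0.10
Max AP: AP thresh/AP amp,1.67,0.11
ct: AHP amplitude (mV),1.18,0.19
Max AP: AHP amplitude (mV),1.09,0.33
ct: AP threshold (mV),1.05,0.03
Max AP: AP threshold (mV),1.03,0.05
2xct: AP threshold (mV),1.00,0.03
2xct: amp 2nd/3rd AP,0.98,0.03
Max AP: amp 2nd/3rd AP,0.90,0.04
2xct: AHP amplitude (mV),0.85,0.17
2xct: amp 1st/last AP,0.76,0.03
Max AP: amp 1st/last AP,0.75,0.06
Max AP: amp 1st/2nd AP,0.73,0.03
2xct: amp 1st/2nd AP,0.69,0.03
ct: AP amplitude (mV),0.64,0.03
Max AP: AP amplitude (mV),0.64,0.04
2xct: AP amplitude (mV),0.62,0.03
Mean ADP value (mV),0.87,0.29
ADP probability,0.84,0.08
ct: AHP latency (ms),0.67,0.15
2xct: Cv2:all,0.66,0.10
2xct: latency to first AP (ms),0.64,0.12
2xct: Cv2-1st/2nd AP,0.62,0.08
2xct: Cv2-1st AP,0.61,0.07
Max AP: Cv2-1st/2nd AP,0.60,0.17
Max AP: Cv2-1st AP,0.59,0.16
Max AP: latency to first AP (ms),0.51,0.08
Max AP: Cv2:all,0.51,0.14
2xct: AHP latency (ms),0.26,0.02
Max AP: AHP latency (ms),0.25,0.02
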