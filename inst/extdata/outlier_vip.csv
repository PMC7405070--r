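index,label,value
1,RMP (mV),-64.9
2,Rm (MΩ),755
3,ct,30.0
4,ADP probability,1.00
5,Mean ADP value (mV),0.99
6,Max initial adaptation change (Hz/pA),5.67
7,Max adaptation change relative to ct,3.33
8,Initial adaptation change (2) (Hz/pA),5.67
9,Max adaptation change relative to ct (2),3.33
10,AHP amplitude (mV),-7.78
11,AHP latency (ms),4.12
12,Max AP rise (mV/ms),172
13,Max AP decay (mV/ms),-48.4
14,AP half-width (ms),1.61
15,AP threshold (mV),-39.8
16,AP amplitude (mV),76.7
17,2xct: number of AP,8.00
18,2xct: latency to first AP,17.0
19,2xct: AHP amplitude (mV),-2.98
20,2xct: AHP latency (ms),3.86
21,2xct: max AP rise (mV/ms),169
22,2xct: max AP decay (mV/ms),-46.9
23,2xct: AP half-width (ms),1.64
24,2xct: AP threshold (mV),-41.7
25,2xct: AP amplitude (mV),77.3
26,2xct: 1st/2nd AP ratio,1.15
27,2xct: 2nd/3rd AP ratio,1.01
28,2xct: 1st/last AP ratio,1.18
29,2xct: initial instant frequency,16.0
30,2xct: max adaptation (Hz),2.49
31,2xct: ISI ratio,0.46
32,2xct: mean of first 2 ISI (ms),133
33,2xct: SD of first 2 ISI (ms),99.4
34,2xct: change of ISI duration from 1st to 2nd AP (ms),141
35,2xct: change of instant frequency from 1st to 2nd AP pair (Hz),-11.1
36,2xct: Cv2:all,0.86
37,2xct: Cv2-1st AP,0.82
38,2xct: Cv2-1st/2nd AP,0.92
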