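set,index,label,unit,level,family,lo,hi,map63,aliases
38,1,RMP (mV),mV,base,normal,,,1,RMP
38,2,Rm (MΩ),MΩ,base,lognormal,1,,2,Rm|Rm (MOhm)
38,3,ct,pA,base,normal,10,,3,ct (pA)|Current threshold (ct:pA)
38,4,ADP probability,probability,ct,normal,0,1,,
38,5,Mean ADP value (mV),mV,ct,normal,0,,,ADP mean
38,6,Max initial adaptation change (Hz/pA),Hz/pA,train,normal,0,,,
38,7,Max adaptation change relative to ct,ratio,train,normal,1,,,
38,8,Initial adaptation change (2) (Hz/pA),Hz/pA,train,normal,0,,,Initial adaptation change (Hz/pA) (2)
38,9,Max adaptation change relative to ct (2),ratio,train,normal,1,,,
38,10,AHP amplitude (mV),mV,ct,normal,,0,4,
38,11,AHP latency (ms),ms,ct,lognormal,0.2,,5,
38,12,Max AP rise (mV/ms),mV/ms,ct,normal,10,,6,
38,13,Max AP decay (mV/ms),mV/ms,ct,normal,,-1,7,
38,14,AP half-width (ms),ms,ct,normal,0.1,,8,
38,15,AP threshold (mV),mV,ct,normal,,,9,
38,16,AP amplitude (mV),mV,ct,normal,20,,10,
38,17,2xct: number of AP,count,2xct,normal,1,,14,2xct: # AP
38,18,2xct: latency to first AP,ms,2xct,lognormal,0.5,,15,2xct: latency to first AP (ms)
38,19,2xct: AHP amplitude (mV),mV,2xct,normal,,0,16,
38,20,2xct: AHP latency (ms),ms,2xct,lognormal,0.2,,17,2xct: AHP amplitude latency (ms)|2xct: AHP latency
38,21,2xct: max AP rise (mV/ms),mV/ms,2xct,normal,10,,18,
38,22,2xct: max AP decay (mV/ms),mV/ms,2xct,normal,,-1,19,
38,23,2xct: AP half-width (ms),ms,2xct,normal,0.1,,20,
38,24,2xct: AP threshold (mV),mV,2xct,normal,,,21,
38,25,2xct: AP amplitude (mV),mV,2xct,normal,20,,22,
38,26,2xct: 1st/2nd AP ratio,ratio,2xct,normal,0.1,,26,2xct: amp 1st/2nd AP
38,27,2xct: 2nd/3rd AP ratio,ratio,2xct,normal,0.1,,27,2xct: amp 2nd/3rd AP
38,28,2xct: 1st/last AP ratio,ratio,2xct,normal,0.1,,28,2xct: 1st /last AP ratio|2xct: amp 1st /last AP
38,29,2xct: initial instant frequency,Hz,2xct,normal,1,,29,2xct: initial instant frequency (Hz)
38,30,2xct: max adaptation (Hz),Hz,2xct,normal,,,30,2xct: adaptation (Hz)
38,31,2xct: ISI ratio,ratio,2xct,normal,0,,31,
38,32,2xct: mean of first 2 ISI (ms),ms,2xct,normal,1,,32,2xct: average initial burst interval (ms) first 3 AP|2xct: average initial burst interva (ms) first 3 AP
38,33,2xct: SD of first 2 ISI (ms),ms,2xct,lognormal,0.05,,33,2xct: SD of average initial burst interval first 3 AP|2xct: SD of average initial burstinterval first 3 AP
38,34,2xct: change of ISI duration from 1st to 2nd AP (ms),ms,2xct,normal,,,34,2xct: change of initial interspike interval (ms)|2xct: change of ISI durationfrom 1stto 2nd AP (ms)
38,35,2xct: change of instant frequency from 1st to 2nd AP pair (Hz),Hz,2xct,normal,,,35,2xct: initial change of instant frequency|2xct: change of instant frequencyfrom 1st to 2nd AP pair (Hz)
38,36,2xct: Cv2:all,dimensionless,2xct,lognormal,0,2,36,
38,37,2xct: Cv2-1st AP,dimensionless,2xct,lognormal,0,2,37,
38,38,2xct: Cv2-1st/2nd AP,dimensionless,2xct,lognormal,0,2,38,
63,1,RMP (mV),mV,base,normal,,,,RMP
63,2,Rm (MΩ),MΩ,base,lognormal,1,,,Rm|Rm (MOhm)
63,3,current threshold (ct: pA),pA,base,normal,10,,,ct (pA)|Current threshold (ct:pA)
63,4,ct: AHP amplitude (mV),mV,ct,normal,,0,,
63,5,ct: AHP latency (ms),ms,ct,lognormal,0.2,,,
63,6,ct: max AP rise (mV/ms),mV/ms,ct,normal,10,,,
63,7,ct: max AP decay (mV/ms),mV/ms,ct,normal,,-1,,
63,8,ct: AP half-width (ms),ms,ct,normal,0.1,,,
63,9,ct: AP threshold (mV),mV,ct,normal,,,,
63,10,ct: AP amplitude (mV),mV,ct,normal,20,,,
63,11,ct: AP rise/decay ratio,ratio,ct,normal,0.1,,,
63,12,ct: AP threshold/AP amp.,ratio,ct,normal,,0,,ct: AP threshold/AP amp|ct: AP thresh/AP amp
63,13,ct: AP rise/AP half-width,mV/ms^2,ct,normal,1,,,ct: AP rise/ AP half-width
63,14,2xct: # AP,count,2xct,normal,1,,,
63,15,2xct: latency to first AP (ms),ms,2xct,lognormal,0.5,,,2xct: latency to first AP
63,16,2xct: AHP amplitude (mV),mV,2xct,normal,,0,,
63,17,2xct: AHP latency (ms),ms,2xct,lognormal,0.2,,,2xct: AHP latency
63,18,2xct: max AP rise (mV/ms),mV/ms,2xct,normal,10,,,
63,19,2xct: max AP decay (mV/ms),mV/ms,2xct,normal,,-1,,
63,20,2xct: AP half-width (ms),ms,2xct,normal,0.1,,,
63,21,2xct: AP threshold (mV),mV,2xct,normal,,,,
63,22,2xct: AP amplitude (mV),mV,2xct,normal,20,,,
63,23,2xct: AP rise/decay ratio,ratio,2xct,normal,0.1,,,
63,24,2xct: AP thresh/AP ampl,ratio,2xct,normal,,0,,2xct: AP thresh/AP amp|2xct: AP threshold/AP amp.
63,25,2xct: AP rise/AP half-width,mV/ms^2,2xct,normal,1,,,2xct: AP rise/ AP half-width
63,26,2xct: amp 1st/2nd AP,ratio,2xct,normal,0.1,,,
63,27,2xct: amp 2nd/3rd AP,ratio,2xct,normal,0.1,,,
63,28,2xct: amp 1st/last AP,ratio,2xct,normal,0.1,,,2xct: amp 1st /last AP
63,29,2xct: initial instant frequency (Hz),Hz,2xct,normal,1,,,2xct: initial instantaneous frequency
63,30,2xct: adaptation (Hz),Hz,2xct,normal,,,,
63,31,2xct: ISI ratio,ratio,2xct,normal,0,,,
63,32,2xct: mean of first 2 ISI (ms),ms,2xct,normal,1,,,
63,33,2xct: SD of first 2 ISI (ms),ms,2xct,lognormal,0.05,,,
63,34,2xct: change of ISI duration from 1st to 2nd AP (ms),ms,2xct,normal,,,,2xct: change of ISI durationfrom 1st to 2nd AP (ms)
63,35,2xct: change of instant frequency from 1st to 2nd AP pair (Hz),Hz,2xct,normal,,,,2xct: change of instant frequencyfrom 1st to 2nd AP pair (Hz)
63,36,2xct: Cv2:all,dimensionless,2xct,lognormal,0,2,,
63,37,2xct: Cv2-1st AP,dimensionless,2xct,lognormal,0,2,,
63,38,2xct: Cv2-1st/2nd AP,dimensionless,2xct,lognormal,0,2,,
63,39,Max AP: # AP,count,max,normal,1,,,
63,40,Max AP: latency to first AP (ms),ms,max,lognormal,0.2,,,max AP: latency to first AP (ms)
63,41,Max AP: AHP amplitude (mV),mV,max,normal,,0,,
63,42,Max AP: AHP latency (ms),ms,max,lognormal,0.2,,,
63,43,Max AP: max AP rise (mV/ms),mV/ms,max,normal,10,,,
63,44,Max AP: max AP decay (mV/ms),mV/ms,max,normal,,-1,,max AP: max AP decay (mV/ms)
63,45,Max AP: AP half-width (ms),ms,max,normal,0.1,,,
63,46,Max AP: AP threshold (mV),mV,max,normal,,,,
63,47,Max AP: AP amplitude (mV),mV,max,normal,20,,,
63,48,Max AP: AP rise/decay ratio,ratio,max,normal,0.1,,,
63,49,Max AP: AP thresh/AP amp,ratio,max,normal,,0,,Max AP: AP thresh/AP ampl
63,50,Max AP: AP rise/AP half-width,mV/ms^2,max,normal,1,,,Max AP: AP rise/ AP half-width
63,51,Max AP: amp 1st/2nd AP,ratio,max,normal,0.1,,,Max AP: 1st/2nd AP ratio
63,52,Max AP: amp 2nd/3rd AP,ratio,max,normal,0.1,,,Max AP: 2nd/3rd AP ratio
63,53,Max AP: amp 1st/last AP,ratio,max,normal,0.1,,,Max AP: amp 1st /last AP
63,54,Max AP: initial instant frequency (Hz),Hz,max,normal,1,,,Max AP: initial instantaneous frequency
63,55,Max AP: adaptation (Hz),Hz,max,normal,,,,
63,56,Max AP: ISI ratio,ratio,max,normal,0,,,
63,57,Max AP: mean of first 2 ISI (ms),ms,max,normal,1,,,Max AP: Mean of first 2 ISI (ms)
63,58,Max AP: SD of first 2 ISI (ms),ms,max,lognormal,0.02,,,Max AP:SD of first 2 ISI (ms)
63,59,Max AP: change of ISI duration from 1st to 2nd AP (ms),ms,max,normal,,,,Max AP: Change of ISI duration from 1st to 2nd AP (ms)
63,60,Max AP: change of instant frequency from 1st to 2nd AP pair (Hz),Hz,max,normal,,,,Max AP: change of instantaneous frequency from 1st to 2nd AP pair (Hz)
63,61,Max AP: Cv2:all,dimensionless,max,lognormal,0,2,,
63,62,Max AP: Cv2-1st AP,dimensionless,max,lognormal,0,2,,
63,63,Max AP: Cv2-1st/2nd AP,dimensionless,max,lognormal,0,2,,
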