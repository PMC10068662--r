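local_label,domain,vocabulary,concept_id,concept_name
MAP,Measurement,LOINC,3004249,Mean blood pressure
SBP,Measurement,LOINC,3004949,Systolic blood pressure
DBP,Measurement,LOINC,3012888,Diastolic blood pressure
HR,Measurement,LOINC,3027018,Heart rate
SPO2,Measurement,LOINC,3016502,Oxygen saturation by pulse oximetry
ETCO2,Measurement,LOINC,3020716,Carbon dioxide in exhaled gas end expiration
TV,Measurement,LOINC,3024929,Tidal volume setting ventilator
mmHg,Unit,UCUM,8876,millimeter mercury column
bpm,Unit,UCUM,8541,beats per minute
%,Unit,UCUM,8554,percent
mL,Unit,UCUM,8587,milliliter
mg,Unit,UCUM,8576,milligram
propofol,Drug,RxNorm,753626,propofol
sufentanil,Drug,RxNorm,19078219,sufentanil
cefazolin,Drug,RxNorm,1771162,cefazolin
ephedrine,Drug,RxNorm,1195334,ephedrine
atracurium,Drug,RxNorm,19003953,atracurium
norepinephrine,Drug,RxNorm,550667,norepinephrine
ketamine,Drug,RxNorm,785649,ketamine
dexamethasone,Drug,RxNorm,1518254,dexamethasone
anesthesia start,Observation,local,2000000201,anesthesia start milestone
anesthesia end,Observation,local,2000000202,anesthesia end milestone
surgery start,Observation,local,2000000203,surgery start milestone
surgery end,Observation,local,2000000204,surgery end milestone
operating room,Visit,local,2000000101,operating room passage
intensive care,Visit,SNOMED,32037,Intensive Care
ward,Visit,SNOMED,9201,Inpatient Visit
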