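patient_id,date,kind
P02,2016-03-20,surgery
P03,2016-04-01,surgery
P09,2016-08-10,surgery
P10,2016-05-01,surgery
P11,2016-03-25,surgery
P19,2016-08-25,surgery
P21,2016-05-10,surgery
P22,2016-06-25,surgery
P26,2016-06-20,surgery
P28,2016-09-04,hsct
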