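patient_id,date,drug_id,drug_class,route,dose_mg
P01,2016-03-01,s1,chemotherapy,PO,120
P01,2016-03-02,s1,chemotherapy,PO,120
P01,2016-03-03,s1,chemotherapy,PO,120
P01,2016-03-04,s1,chemotherapy,PO,120
P01,2016-03-05,s1,chemotherapy,PO,120
P01,2016-03-06,s1,chemotherapy,PO,120
P01,2016-03-07,s1,chemotherapy,PO,120
P01,2016-03-08,aprepitant,NK1,PO,125
P01,2016-03-08,cisplatin,chemotherapy,IV,89
P01,2016-03-08,dexamethasone,steroid,IV,9.9
P01,2016-03-08,granisetron,serotonin_antagonist,IV,3
P01,2016-03-08,s1,chemotherapy,PO,120
P02,2016-04-01,cyclophosphamide,chemotherapy,IV,888
P02,2016-04-01,dexamethasone,steroid,IV,9.9
P02,2016-04-01,doxorubicin,chemotherapy,IV,89
P02,2016-04-01,granisetron,serotonin_antagonist,IV,3
P03,2016-04-21,dexamethasone,steroid,PO,8
P03,2016-05-01,capecitabine,chemotherapy,PO,3600
P03,2016-05-02,capecitabine,chemotherapy,PO,3600
P03,2016-05-03,capecitabine,chemotherapy,PO,3600
P03,2016-05-04,capecitabine,chemotherapy,PO,3600
P03,2016-05-05,capecitabine,chemotherapy,PO,3600
P03,2016-05-06,capecitabine,chemotherapy,PO,3600
P03,2016-05-07,capecitabine,chemotherapy,PO,3600
P03,2016-05-08,capecitabine,chemotherapy,PO,3600
P04,2016-02-15,aprepitant,NK1,PO,125
P04,2016-02-15,carboplatin,chemotherapy,IV,600
P04,2016-02-15,granisetron,serotonin_antagonist,IV,3
P04,2016-02-15,paclitaxel,chemotherapy,IV,296
P05,2016-06-01,cyclophosphamide,chemotherapy,IV,1110
P05,2016-06-01,doxorubicin,chemotherapy,IV,74
P05,2016-06-01,prednisolone,steroid,PO,100
P05,2016-06-01,rituximab,chemotherapy,IV,550
P05,2016-06-01,vincristine,chemotherapy,IV,2
P05,2016-06-02,prednisolone,steroid,PO,100
P05,2016-06-03,prednisolone,steroid,PO,100
P05,2016-06-04,prednisolone,steroid,PO,100
P05,2016-06-05,prednisolone,steroid,PO,100
P06,2016-03-10,aprepitant,NK1,PO,125
P06,2016-03-10,cisplatin,chemotherapy,IV,104
P06,2016-03-10,dexamethasone,steroid,IV,9.9
P06,2016-03-10,fluorouracil,chemotherapy,IV,1184
P06,2016-03-10,granisetron,serotonin_antagonist,IV,3
P06,2016-03-11,fluorouracil,chemotherapy,IV,1184
P06,2016-03-12,fluorouracil,chemotherapy,IV,1184
P06,2016-03-13,fluorouracil,chemotherapy,IV,1184
P06,2016-03-14,fluorouracil,chemotherapy,IV,1184
P07,2016-07-01,fluorouracil,chemotherapy,IV,3552
P07,2016-07-01,granisetron,serotonin_antagonist,IV,3
P07,2016-07-01,irinotecan,chemotherapy,IV,266
P07,2016-07-01,levofolinate,chemotherapy,IV,296
P07,2016-07-01,oxaliplatin,chemotherapy,IV,126
P08,2016-08-01,cisplatin,chemotherapy,IV,118
P08,2016-08-01,etoposide,chemotherapy,IV,148
P08,2016-08-02,etoposide,chemotherapy,IV,148
P08,2016-08-03,etoposide,chemotherapy,IV,148
P09,2016-09-01,s1,chemotherapy,PO,120
P09,2016-09-02,s1,chemotherapy,PO,120
P09,2016-09-03,s1,chemotherapy,PO,120
P09,2016-09-04,s1,chemotherapy,PO,120
P09,2016-09-05,s1,chemotherapy,PO,120
P09,2016-09-06,s1,chemotherapy,PO,120
P09,2016-09-07,s1,chemotherapy,PO,120
P09,2016-09-08,s1,chemotherapy,PO,120
P10,2016-05-20,dexamethasone,steroid,IV,6.6
P10,2016-05-20,trastuzumab,chemotherapy,IV,518
P11,2016-04-10,dexamethasone,steroid,IV,9.9
P11,2016-04-10,fluorouracil,chemotherapy,IV,3500
P11,2016-04-10,granisetron,serotonin_antagonist,IV,3
P11,2016-04-10,levofolinate,chemotherapy,IV,296
P11,2016-04-10,oxaliplatin,chemotherapy,IV,126
P11,2016-04-11,fluorouracil,chemotherapy,IV,3500
P12,2016-03-05,dexamethasone,steroid,IV,9.9
P12,2016-03-05,gemcitabine,chemotherapy,IV,1480
P12,2016-03-05,granisetron,serotonin_antagonist,IV,3
P12,2016-03-05,nab-paclitaxel,chemotherapy,IV,185
P12,2016-03-12,gemcitabine,chemotherapy,IV,1480
P12,2016-03-12,nab-paclitaxel,chemotherapy,IV,185
P13,2016-02-20,rituximab,chemotherapy,IV,550
P14,2016-06-10,gefitinib,chemotherapy,PO,250
P14,2016-06-11,gefitinib,chemotherapy,PO,250
P14,2016-06-12,gefitinib,chemotherapy,PO,250
P14,2016-06-13,gefitinib,chemotherapy,PO,250
P14,2016-06-14,gefitinib,chemotherapy,PO,250
P14,2016-06-15,gefitinib,chemotherapy,PO,250
P14,2016-06-16,gefitinib,chemotherapy,PO,250
P14,2016-06-17,gefitinib,chemotherapy,PO,250
P15,2016-05-15,dexamethasone,steroid,IV,9.9
P15,2016-05-15,granisetron,serotonin_antagonist,IV,3
P15,2016-05-15,oxaliplatin,chemotherapy,IV,148
P15,2016-05-15,s1,chemotherapy,PO,120
P15,2016-05-16,s1,chemotherapy,PO,120
P15,2016-05-17,s1,chemotherapy,PO,120
P15,2016-05-18,s1,chemotherapy,PO,120
P15,2016-05-19,s1,chemotherapy,PO,120
P15,2016-05-20,s1,chemotherapy,PO,120
P15,2016-05-21,s1,chemotherapy,PO,120
P15,2016-05-22,s1,chemotherapy,PO,120
P16,2016-04-20,aprepitant,NK1,PO,125
P16,2016-04-20,cisplatin,chemotherapy,IV,104
P16,2016-04-20,dexamethasone,steroid,IV,9.9
P16,2016-04-20,docetaxel,chemotherapy,IV,89
P16,2016-04-20,fluorouracil,chemotherapy,IV,1110
P16,2016-04-20,granisetron,serotonin_antagonist,IV,3
P16,2016-04-21,fluorouracil,chemotherapy,IV,1110
P16,2016-04-22,fluorouracil,chemotherapy,IV,1110
P16,2016-04-23,fluorouracil,chemotherapy,IV,1110
P16,2016-04-24,fluorouracil,chemotherapy,IV,1110
P17,2016-07-15,carboplatin,chemotherapy,IV,625
P17,2016-07-15,dexamethasone,steroid,IV,9.9
P17,2016-07-15,etoposide,chemotherapy,IV,148
P17,2016-07-15,granisetron,serotonin_antagonist,IV,3
P17,2016-07-16,etoposide,chemotherapy,IV,148
P17,2016-07-17,etoposide,chemotherapy,IV,148
P18,2016-08-10,aprepitant,NK1,PO,125
P18,2016-08-10,dexamethasone,steroid,IV,9.9
P18,2016-08-10,fluorouracil,chemotherapy,IV,4800
P18,2016-08-10,granisetron,serotonin_antagonist,IV,3
P18,2016-08-10,irinotecan,chemotherapy,IV,245
P18,2016-08-10,levofolinate,chemotherapy,IV,296
P18,2016-08-10,oxaliplatin,chemotherapy,IV,126
P19,2016-09-10,dexamethasone,steroid,IV,9.9
P19,2016-09-10,paclitaxel,chemotherapy,IV,133
P19,2016-09-17,paclitaxel,chemotherapy,IV,133
P20,2016-10-01,aprepitant,NK1,PO,125
P20,2016-10-01,cisplatin,chemotherapy,IV,118
P20,2016-10-01,dexamethasone,steroid,IV,9.9
P20,2016-10-01,granisetron,serotonin_antagonist,IV,3
P21,2016-05-02,dexamethasone,steroid,PO,8
P21,2016-06-01,folinate,chemotherapy,PO,75
P21,2016-06-01,uft,chemotherapy,PO,400
P21,2016-06-02,folinate,chemotherapy,PO,75
P21,2016-06-02,uft,chemotherapy,PO,400
P21,2016-06-03,folinate,chemotherapy,PO,75
P21,2016-06-03,uft,chemotherapy,PO,400
P21,2016-06-04,folinate,chemotherapy,PO,75
P21,2016-06-04,uft,chemotherapy,PO,400
P21,2016-06-05,folinate,chemotherapy,PO,75
P21,2016-06-05,uft,chemotherapy,PO,400
P21,2016-06-06,folinate,chemotherapy,PO,75
P21,2016-06-06,uft,chemotherapy,PO,400
P21,2016-06-07,folinate,chemotherapy,PO,75
P21,2016-06-07,uft,chemotherapy,PO,400
P21,2016-06-08,folinate,chemotherapy,PO,75
P21,2016-06-08,uft,chemotherapy,PO,400
P22,2016-06-09,granisetron,serotonin_antagonist,PO,2
P22,2016-07-10,s1,chemotherapy,PO,120
P22,2016-07-11,s1,chemotherapy,PO,120
P22,2016-07-12,s1,chemotherapy,PO,120
P22,2016-07-13,s1,chemotherapy,PO,120
P22,2016-07-14,s1,chemotherapy,PO,120
P22,2016-07-15,s1,chemotherapy,PO,120
P22,2016-07-16,s1,chemotherapy,PO,120
P22,2016-07-17,s1,chemotherapy,PO,120
P23,2016-03-20,dexamethasone,steroid,IV,6.6
P23,2016-03-20,methotrexate,chemotherapy,IV,59.2
P24,2016-04-05,cyclophosphamide,chemotherapy,IV,2960
P24,2016-04-05,dexamethasone,steroid,IV,9.9
P24,2016-04-05,granisetron,serotonin_antagonist,IV,3
P25,2016-05-05,cisplatin,chemotherapy,IV,118
P25,2016-05-05,interferon-alpha,chemotherapy,IV,600
P26,2016-06-20,fluorouracil,chemotherapy,IV,3500
P26,2016-06-20,levofolinate,chemotherapy,IV,296
P26,2016-06-20,oxaliplatin,chemotherapy,IV,126
P27,2016-07-20,cisplatin,chemotherapy,arterial,59
P28,2016-08-15,carboplatin,chemotherapy,IV,625
P28,2016-08-15,etoposide,chemotherapy,IV,148
P28,2016-08-15,ifosfamide,chemotherapy,IV,1850
P29,2016-09-20,cyclophosphamide,chemotherapy,IV,888
P29,2016-09-20,doxorubicin,chemotherapy,IV,89
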