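patient_id,sex,age_at_dx,cancer_type,dx_date,clinical_stage,pathological_stage,resection_date,adjuvant_flag
P01,male,68,gastric,2016-02-01,III,unknown,NA,FALSE
P02,female,54,breast,2016-03-01,II,II,2016-03-20,TRUE
P03,female,61,colorectal,2016-03-15,III,II,2016-04-01,TRUE
P04,male,70,non_small_cell_lung,2016-01-20,IV,unknown,NA,FALSE
P05,male,66,malignant_lymphoma,2016-05-01,III,unknown,NA,FALSE
P06,male,72,oesophageal,2016-02-15,III,unknown,NA,FALSE
P07,female,58,pancreatic,2016-06-01,IV,unknown,NA,FALSE
P08,male,69,small_cell_lung,2016-07-01,IV,unknown,NA,FALSE
P09,female,75,gastric,2016-08-01,II,II,2016-08-10,TRUE
P10,female,49,breast,2016-04-20,I,I,2016-05-01,TRUE
P11,male,63,colorectal,2016-03-10,III,III,2016-03-25,TRUE
P12,male,67,pancreatic,2016-02-10,IV,unknown,NA,FALSE
P13,female,71,malignant_lymphoma,2016-01-25,I,unknown,NA,FALSE
P14,female,77,non_small_cell_lung,2016-05-15,IV,unknown,NA,FALSE
P15,male,60,gastric,2016-04-15,III,unknown,NA,FALSE
P16,male,64,oesophageal,2016-03-20,II,unknown,NA,FALSE
P17,male,73,small_cell_lung,2016-06-20,III,unknown,NA,FALSE
P18,female,55,colorectal,2016-07-10,IV,unknown,NA,FALSE
P19,female,52,breast,2016-08-15,II,II,2016-08-25,TRUE
P20,male,65,other,2016-09-01,III,unknown,NA,FALSE
P21,male,59,colorectal,2016-05-01,II,II,2016-05-10,TRUE
P22,female,62,gastric,2016-06-15,II,II,2016-06-25,TRUE
P23,male,48,other,2016-02-25,II,unknown,NA,FALSE
P24,female,57,other,2016-03-05,III,unknown,NA,FALSE
P25,male,66,other,2016-04-10,IV,unknown,NA,FALSE
P26,female,61,colorectal,2016-05-20,III,unknown,NA,FALSE
P27,male,70,other,2016-06-25,IV,unknown,NA,FALSE
P28,male,45,malignant_lymphoma,2016-07-20,III,unknown,NA,FALSE
P29,female,19,breast,2016-08-20,II,unknown,NA,FALSE
P30,male,80,gastric,2016-09-10,I,unknown,NA,FALSE
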