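# rules_version: 2016.1 drug canonicalization dictionary
raw_name,drug_id,drug_class
cisplatin,cisplatin,chemotherapy
CDDP,cisplatin,chemotherapy
carboplatin,carboplatin,chemotherapy
CBDCA,carboplatin,chemotherapy
oxaliplatin,oxaliplatin,chemotherapy
L-OHP,oxaliplatin,chemotherapy
nedaplatin,nedaplatin,chemotherapy
irinotecan,irinotecan,chemotherapy
CPT11,irinotecan,chemotherapy
CPT-11,irinotecan,chemotherapy
fluorouracil,fluorouracil,chemotherapy
5-FU,fluorouracil,chemotherapy
levofolinate,levofolinate,chemotherapy
l-LV,levofolinate,chemotherapy
folinate,folinate,chemotherapy
LV,folinate,chemotherapy
doxorubicin,doxorubicin,chemotherapy
ADM,doxorubicin,chemotherapy
epirubicin,epirubicin,chemotherapy
epirubicine,epirubicin,chemotherapy
EPI,epirubicin,chemotherapy
cyclophosphamide,cyclophosphamide,chemotherapy
CPA,cyclophosphamide,chemotherapy
CPM,cyclophosphamide,chemotherapy
ifosfamide,ifosfamide,chemotherapy
cytarabine,cytarabine,chemotherapy
methotrexate,methotrexate,chemotherapy
MTX,methotrexate,chemotherapy
gemcitabine,gemcitabine,chemotherapy
GEM,gemcitabine,chemotherapy
docetaxel,docetaxel,chemotherapy
DTX,docetaxel,chemotherapy
paclitaxel,paclitaxel,chemotherapy
PTX,paclitaxel,chemotherapy
nab-paclitaxel,nab-paclitaxel,chemotherapy
nab-PTX,nab-paclitaxel,chemotherapy
mitomycin,mitomycin,chemotherapy
mitomycin C,mitomycin,chemotherapy
etoposide,etoposide,chemotherapy
pemetrexed,pemetrexed,chemotherapy
vincristine,vincristine,chemotherapy
VCR,vincristine,chemotherapy
vinorelbine,vinorelbine,chemotherapy
VNR,vinorelbine,chemotherapy
bleomycin,bleomycin,chemotherapy
procarbazine,procarbazine,chemotherapy
temozolomide,temozolomide,chemotherapy
imatinib,imatinib,chemotherapy
nimustine,nimustine,chemotherapy
ranimustine,ranimustine,chemotherapy
S-1,s1,chemotherapy
S1,s1,chemotherapy
TS-1,s1,chemotherapy
s1,s1,chemotherapy
tegafur/gimeracil/oteracil,s1,chemotherapy
UFT,uft,chemotherapy
uft,uft,chemotherapy
tegafur/uracil,uft,chemotherapy
capecitabine,capecitabine,chemotherapy
lenalidomide,lenalidomide,chemotherapy
afatinib,afatinib,chemotherapy
dasatinib,dasatinib,chemotherapy
sunitinib,sunitinib,chemotherapy
gefitinib,gefitinib,chemotherapy
erlotinib,erlotinib,chemotherapy
sorafenib,sorafenib,chemotherapy
regorafenib,regorafenib,chemotherapy
hydroxycarbamide,hydroxycarbamide,chemotherapy
bortezomib,bortezomib,chemotherapy
rituximab,rituximab,chemotherapy
trastuzumab,trastuzumab,chemotherapy
cetuximab,cetuximab,chemotherapy
nelarabine,nelarabine,chemotherapy
panitumumab,panitumumab,chemotherapy
pertuzumab,pertuzumab,chemotherapy
ramucirumab,ramucirumab,chemotherapy
nivolumab,nivolumab,chemotherapy
interferon-alpha,interferon-alpha,chemotherapy
interferon alpha,interferon-alpha,chemotherapy
aprepitant,aprepitant,NK1
fosaprepitant,fosaprepitant,NK1
granisetron,granisetron,serotonin_antagonist
ondansetron,ondansetron,serotonin_antagonist
palonosetron,palonosetron,serotonin_antagonist
ramosetron,ramosetron,serotonin_antagonist
azasetron,azasetron,serotonin_antagonist
dexamethasone,dexamethasone,steroid
prednisolone,prednisolone,steroid
PSL,prednisolone,steroid
methylprednisolone,methylprednisolone,steroid
betamethasone,betamethasone,steroid
hydrocortisone,hydrocortisone,steroid
metoclopramide,metoclopramide,other
domperidone,domperidone,other
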