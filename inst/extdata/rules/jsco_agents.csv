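# rules_version: 2016.1 guideline: JSCO
drug_id,route,tier_bound,bound_unit,bound_op,category,default_category,fallback_category
cisplatin,IV,,,,high,high,
procarbazine,PO,,,,high,high,
carboplatin,IV,,,,moderate,moderate,
oxaliplatin,IV,,,,moderate,moderate,
epirubicin,IV,,,,moderate,moderate,
doxorubicin,IV,,,,moderate,moderate,
ifosfamide,IV,,,,moderate,moderate,
nedaplatin,IV,,,,moderate,moderate,
nimustine,IV,,,,moderate,moderate,
ranimustine,IV,,,,moderate,moderate,
temozolomide,PO,,,,moderate,moderate,
imatinib,PO,,,,moderate,moderate,
cyclophosphamide,PO,,,,moderate,moderate,
cyclophosphamide,IV,1500,mg_m2,gt,high,moderate,moderate
methotrexate,IV,50,mg_m2,ge,moderate,low,moderate
methotrexate,IV,250,mg_m2,gt,high,low,moderate
cytarabine,IV,200,mg_m2,gt,moderate,low,moderate
irinotecan,IV,,,,low,low,
gemcitabine,IV,,,,low,low,
docetaxel,IV,,,,low,low,
paclitaxel,IV,,,,low,low,
nab-paclitaxel,IV,,,,low,low,
mitomycin,IV,,,,low,low,
fluorouracil,IV,,,,low,low,
etoposide,IV,,,,low,low,
etoposide,PO,,,,low,low,
pemetrexed,IV,,,,low,low,
s1,PO,,,,low,low,
uft,PO,,,,low,low,
capecitabine,PO,,,,low,low,
lenalidomide,PO,,,,low,low,
afatinib,PO,,,,low,low,
dasatinib,PO,,,,low,low,
sunitinib,PO,,,,low,low,
levofolinate,IV,,,,minimal,minimal,
folinate,PO,,,,minimal,minimal,
vincristine,IV,,,,minimal,minimal,
vinorelbine,IV,,,,minimal,minimal,
bortezomib,IV,,,,minimal,minimal,
rituximab,IV,,,,minimal,minimal,
trastuzumab,IV,,,,minimal,minimal,
cetuximab,IV,,,,minimal,minimal,
nelarabine,IV,,,,minimal,minimal,
panitumumab,IV,,,,minimal,minimal,
pertuzumab,IV,,,,minimal,minimal,
ramucirumab,IV,,,,minimal,minimal,
nivolumab,IV,,,,minimal,minimal,
gefitinib,PO,,,,minimal,minimal,
erlotinib,PO,,,,minimal,minimal,
sorafenib,PO,,,,minimal,minimal,
regorafenib,PO,,,,minimal,minimal,
methotrexate,PO,,,,minimal,minimal,
hydroxycarbamide,PO,,,,minimal,minimal,
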