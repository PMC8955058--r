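# rules_version: 2016.1 guideline: MASCC
drug_id,route,tier_bound,bound_unit,bound_op,category,default_category,fallback_category
cisplatin,IV,,,,high,high,
procarbazine,PO,,,,high,high,
carboplatin,IV,,,,moderate,moderate,
cyclophosphamide,IV,1500,mg_m2,gt,high,moderate,moderate
cyclophosphamide,PO,,,,moderate,moderate,
doxorubicin,IV,,,,moderate,moderate,
epirubicin,IV,,,,moderate,moderate,
ifosfamide,IV,,,,moderate,moderate,
imatinib,PO,,,,moderate,moderate,
nedaplatin,IV,,,,moderate,moderate,
nimustine,IV,,,,moderate,moderate,
oxaliplatin,IV,,,,moderate,moderate,
ranimustine,IV,,,,moderate,moderate,
temozolomide,PO,,,,moderate,moderate,
afatinib,PO,,,,low,low,
bortezomib,IV,,,,low,low,
capecitabine,PO,,,,low,low,
cetuximab,IV,,,,low,low,
cytarabine,IV,1000,mg_m2,gt,moderate,low,moderate
dasatinib,PO,,,,low,low,
docetaxel,IV,,,,low,low,
etoposide,IV,,,,low,low,
etoposide,PO,,,,low,low,
fluorouracil,IV,,,,low,low,
gemcitabine,IV,,,,low,low,
irinotecan,IV,,,,low,low,
lenalidomide,PO,,,,low,low,
methotrexate,IV,,,,low,low,
mitomycin,IV,,,,low,low,
nab-paclitaxel,IV,,,,low,low,
paclitaxel,IV,,,,low,low,
panitumumab,IV,,,,low,low,
pemetrexed,IV,,,,low,low,
s1,PO,,,,low,low,
sunitinib,PO,,,,low,low,
uft,PO,,,,low,low,
erlotinib,PO,,,,minimal,minimal,
folinate,PO,,,,minimal,minimal,
gefitinib,PO,,,,minimal,minimal,
hydroxycarbamide,PO,,,,minimal,minimal,
levofolinate,IV,,,,minimal,minimal,
methotrexate,PO,,,,minimal,minimal,
nivolumab,IV,,,,minimal,minimal,
ramucirumab,IV,,,,minimal,minimal,
regorafenib,PO,,,,minimal,minimal,
rituximab,IV,,,,minimal,minimal,
sorafenib,PO,,,,minimal,minimal,
trastuzumab,IV,,,,minimal,minimal,
vincristine,IV,,,,minimal,minimal,
vinorelbine,IV,,,,minimal,minimal,
nelarabine,IV,,,,unknown,unknown,
pertuzumab,IV,,,,unknown,unknown,
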