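# rules_version: 2016.1 guideline: JSCO
name,components,route,cancer_context,category
FOLFOXIRI,fluorouracil|levofolinate|oxaliplatin|irinotecan,,colorectal,high
FOLFIRINOX,fluorouracil|levofolinate|oxaliplatin|irinotecan,,pancreatic,high
GS,gemcitabine|s1,,pancreatic,moderate
GEM-nabPTX,gemcitabine|nab-paclitaxel,,pancreatic,moderate
ICE,ifosfamide|carboplatin|etoposide,,malignant_lymphoma,high
AC,doxorubicin|cyclophosphamide,IV,,high
EC,epirubicin|cyclophosphamide,IV,,high
oral-etoposide,etoposide,PO,malignant_lymphoma,moderate
nimustine-ml,nimustine,,malignant_lymphoma,moderate
ranimustine-ml,ranimustine,,malignant_lymphoma,moderate
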