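# Reference knowledge base: physicochemical properties and published delivery labels of
# chemotherapeutic drugs historically administered to DIPG patients.
# Columns: name (as printed), drug_class, log_p (octanol/water partition coefficient,
# dimensionless), molecular_weight_g_per_mol, charge_percent (percent of molecules carrying
# a net charge at pH 7.4), charge_sign (sign of that charge; zwitterionic = simultaneous
# + and -), is_prodrug, oral_only, compound_flags (semicolon-separated), published_systemic
# and published_ced (reference labels: + likely/suitable, +/- intermediate/speculative,
# - unlikely/unsuitable), footnotes (markers as printed).
# Footnote encoding (the printed markers are inconsistently attached; interpretations below):
#   a = prodrug (cyclophosphamide, dacarbazine, ifosfamide).
#   b = physicochemically suitable for CED but only available as an oral formulation.
#   c on irinotecan = prodrug marker (irinotecan is the prodrug of SN-38); is_prodrug TRUE.
#   c on vorinostat = no licensed parenteral formulation; encoded oral_only TRUE.
#   capecitabine carries only footnote b in print but is the prodrug of 5-fluorouracil;
#   is_prodrug TRUE.
# Missing numeric values are empty cells (printed "Unknown"/"na"), never sentinel numbers.
name,drug_class,log_p,molecular_weight_g_per_mol,charge_percent,charge_sign,is_prodrug,oral_only,compound_flags,published_systemic,published_ced,footnotes
Carmustine,alkylating,1.53,214.10,0,neutral,FALSE,FALSE,,+,+,
Cyclophosphamide,alkylating,0.20,277.09,0,neutral,TRUE,FALSE,,+/-,-,a
Dacarbazine,alkylating,-0.5,126.12,0,neutral,TRUE,FALSE,,+/-,-,a
Ifosfamide,alkylating,0.20,277.09,0,neutral,TRUE,FALSE,,+/-,-,a
Lomustine,alkylating,2.83,233.70,0,neutral,FALSE,TRUE,,+,-,b
Melphalan,alkylating,-0.5,305.20,99,zwitterionic,FALSE,FALSE,,-,-,
Temozolomide,alkylating,-1.1,194.15,0,neutral,FALSE,TRUE,,+/-,-,b
Etoposide,topoisomerase_inhibitor,0.60,588.56,1,negative,FALSE,FALSE,,+/-,+,
Irinotecan,topoisomerase_inhibitor,3.50,586.70,100,positive,TRUE,FALSE,,+/-,-,c
Topotecan,topoisomerase_inhibitor,-0.88,412.45,100,positive,FALSE,FALSE,,-,-,
Bevacizumab,monoclonal_antibody,,149000.00,,unknown,FALSE,FALSE,biologic,-,-,
Cetuximab,monoclonal_antibody,,145781.60,,unknown,FALSE,FALSE,biologic,-,-,
Nimotuzumab,monoclonal_antibody,,151000.00,,unknown,FALSE,FALSE,biologic,-,-,
Pembrolizumab,monoclonal_antibody,,146286.29,,unknown,FALSE,FALSE,biologic,-,-,
Afatinib,tyrosine_kinase_inhibitor,3.60,485.94,96,positive,FALSE,FALSE,,+/-,-,
Cobimetinib,tyrosine_kinase_inhibitor,3.90,531.32,100,positive,FALSE,FALSE,,+/-,-,
Crenolanib,tyrosine_kinase_inhibitor,3.70,443.54,100,positive,FALSE,FALSE,,+/-,-,
Crizotinib,tyrosine_kinase_inhibitor,3.70,450.34,98,positive,FALSE,FALSE,,+/-,-,
Dasatinib,tyrosine_kinase_inhibitor,3.60,488.01,40,positive,FALSE,FALSE,,+/-,-,
Erlotinib,tyrosine_kinase_inhibitor,2.95,393.44,0,neutral,FALSE,TRUE,,+,-,b
Imatinib,tyrosine_kinase_inhibitor,3.25,493.60,88,positive,FALSE,FALSE,,+/-,-,
Gefitinib,tyrosine_kinase_inhibitor,3.65,446.90,21,positive,FALSE,TRUE,,+/-,-,b
Vandetanib,tyrosine_kinase_inhibitor,4.82,475.35,98,positive,FALSE,FALSE,,+/-,-,
Everolimus,mtor_inhibitor,5.90,958.22,0,neutral,FALSE,TRUE,,-,-,b
Sirolimus,mtor_inhibitor,4.81,914.17,0,neutral,FALSE,TRUE,,-,-,b
Tacrolimus,mtor_inhibitor,3.30,804.02,0,neutral,FALSE,FALSE,,+/-,+,
Temsirolimus,mtor_inhibitor,4.25,1030.29,0,neutral,FALSE,FALSE,,-,+,
Vismodegib,other_signal_transduction,2.70,421.30,0,neutral,FALSE,TRUE,,+,-,b
Dactinomycin,cytotoxic_antibiotic,3.21,1255.42,99,positive,FALSE,FALSE,,-,-,
Daunorubicin,cytotoxic_antibiotic,1.83,527.52,98,positive,FALSE,FALSE,,-,-,
Doxorubicin,cytotoxic_antibiotic,1.28,543.51,98,positive,FALSE,FALSE,,-,-,
Mitoxantrone,cytotoxic_antibiotic,1.19,444.48,99,positive,FALSE,FALSE,,-,-,
Cabazitaxel,antimitotic,2.70,835.93,0,neutral,FALSE,FALSE,,+/-,+,
Vincristine,antimitotic,2.82,824.96,98,positive,FALSE,FALSE,,-,-,
Vinorelbine,antimitotic,4.84,778.93,100,positive,FALSE,FALSE,,-,-,
Capecitabine,antimetabolite,0.56,359.35,12,negative,TRUE,TRUE,,+/-,-,b
Cytarabine,antimetabolite,-2.46,243.22,0,neutral,FALSE,FALSE,,+/-,+,
Gemcitabine,antimetabolite,-2.01,263.19,0,neutral,FALSE,FALSE,,+/-,+,
Methotrexate,antimetabolite,-1.85,454.44,100,negative,FALSE,FALSE,,-,+/-,
Carboplatin,platinum,-0.19,371.25,0,neutral,FALSE,FALSE,platinum_complex,+/-,+,
Cisplatin,platinum,-2.19,300.05,0,neutral,FALSE,FALSE,platinum_complex,+/-,+,
Tamoxifen,antihormone,6.70,371.51,95,positive,FALSE,FALSE,,-,-,
Abemaciclib,other_chemo,3.8,506.59,77,positive,FALSE,FALSE,,-,-,
Cilengitide,other_chemo,-1,588.66,100,positive,FALSE,FALSE,,-,-,
Imetelstat sodium,other_chemo,,4895.95,100,positive,FALSE,FALSE,,-,-,
lenalidomide,other_chemo,-0.4,259.26,0,neutral,FALSE,TRUE,,+,-,b
Panobinostat,other_chemo,3.0,349.43,98,positive,FALSE,FALSE,,+/-,-,
Ribociclib,other_chemo,2.2,434.54,96,positive,FALSE,FALSE,,+/-,-,
Thalidomide,other_chemo,0.33,258.23,0,neutral,FALSE,TRUE,,+,-,b
Veliparib,other_chemo,0.5,244.29,99,positive,FALSE,FALSE,,+/-,-,
Vorinostat,other_chemo,1.44,264.32,3,negative,FALSE,TRUE,,+,-,c
Mebendazole,other_drug,2.83,295.29,8,negative,FALSE,TRUE,,+,-,b
Valproic acid,other_drug,2.75,144.21,99,negative,FALSE,FALSE,,+/-,+/-,
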