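# Efflux transporter substrate annotations for the drugs in dipg_drugs.csv.
# These annotations are attached to reports for completeness only; efflux affinity is
# concentration-dependent and is deliberately NOT used by the classification rules.
# Values: substrate (+), non_substrate (-), ambiguous (+/- in print), unknown (na/blank).
# references: semicolon-separated bibliography numbers of the source reports.
name,pgp,bcrp,mrp1,references
Carmustine,substrate,non_substrate,substrate,6
Cyclophosphamide,substrate,substrate,non_substrate,23;24
Dacarbazine,substrate,unknown,unknown,25
Ifosfamide,substrate,unknown,substrate,26;27
Lomustine,substrate,substrate,substrate,28
Melphalan,substrate,non_substrate,non_substrate,6
Temozolomide,substrate,substrate,non_substrate,6;29
Etoposide,substrate,substrate,substrate,6
Irinotecan,substrate,substrate,substrate,30;31;32
Topotecan,substrate,substrate,substrate,33;34
Bevacizumab,unknown,unknown,unknown,
Cetuximab,unknown,unknown,unknown,
Nimotuzumab,unknown,unknown,unknown,
Pembrolizumab,unknown,unknown,unknown,
Afatinib,substrate,substrate,unknown,25
Cobimetinib,substrate,non_substrate,unknown,25
Crenolanib,unknown,unknown,unknown,
Crizotinib,substrate,non_substrate,substrate,35
Dasatinib,substrate,substrate,substrate,6;36;37
Erlotinib,substrate,substrate,substrate,6;38;39
Imatinib,substrate,substrate,substrate,37;40;41
Gefitinib,substrate,substrate,substrate,31;39;42;43
Vandetanib,substrate,substrate,non_substrate,44;45;46
Everolimus,substrate,non_substrate,unknown,47
Sirolimus,substrate,substrate,unknown,48;49
Tacrolimus,substrate,substrate,unknown,49
Temsirolimus,substrate,non_substrate,non_substrate,6
Vismodegib,substrate,unknown,unknown,50;51
Dactinomycin,substrate,non_substrate,substrate,52;53
Daunorubicin,substrate,substrate,substrate,30
Doxorubicin,substrate,substrate,substrate,6
Mitoxantrone,substrate,substrate,substrate,6
Cabazitaxel,ambiguous,non_substrate,unknown,25
Vincristine,substrate,non_substrate,substrate,30;31;32
Vinorelbine,substrate,unknown,non_substrate,53;54;55
Capecitabine,unknown,unknown,unknown,
Cytarabine,ambiguous,non_substrate,unknown,24;53;56
Gemcitabine,ambiguous,unknown,substrate,24;57
Methotrexate,substrate,substrate,substrate,30;31;58
Carboplatin,substrate,non_substrate,substrate,6;59
Cisplatin,ambiguous,substrate,substrate,23
Tamoxifen,substrate,substrate,non_substrate,60;61;62;63
Abemaciclib,substrate,substrate,unknown,
Cilengitide,substrate,unknown,unknown,64
Imetelstat sodium,unknown,unknown,unknown,
Lenalidomide,substrate,non_substrate,non_substrate,25
Panobinostat,non_substrate,unknown,non_substrate,65
Ribociclib,unknown,unknown,unknown,
Thalidomide,ambiguous,unknown,unknown,66
Veliparib,substrate,substrate,unknown,67;68;69
Vorinostat,unknown,unknown,unknown,65
Mebendazole,non_substrate,unknown,unknown,25
Valproic acid,non_substrate,non_substrate,substrate,70;71;72
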