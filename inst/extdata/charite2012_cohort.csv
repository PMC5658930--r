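patient_id,arm,drug_a,class_a,drug_b,class_b,avastin,response,score
mono_01,mono,Carboplatin,ER,,,no,non_responder,
mono_02,mono,Caelyx,SR,,,no,non_responder,
mono_03,mono,Topotecan,SR,,,no,non_responder,
mono_04,mono,Carboplatin,SR,,,no,non_responder,
mono_05,mono,Topotecan,MR,,,no,non_responder,
mono_06,mono,Topotecan,MR,,,no,non_responder,
mono_07,mono,Caelyx,MR,,,no,non_responder,
mono_08,mono,Caelyx,ER,,,no,non_responder,
mono_09,mono,Caelyx,MR,,,no,non_responder,
mono_10,mono,Topotecan,SR,,,no,non_responder,
mono_11,mono,Topotecan,ER,,,no,non_responder,
mono_12,mono,Topotecan,ER,,,no,non_responder,
mono_13,mono,Paclitaxel,SR,,,no,responder,
mono_14,mono,Carboplatin,SR,,,no,responder,
mono_15,mono,Topotecan,SR,,,no,responder,
mono_16,mono,Paclitaxel,MR,,,no,responder,
monoav_01,mono_plus_avastin,Caelyx,SR,,,yes,non_responder,
monoav_02,mono_plus_avastin,Caelyx,SR,,,yes,responder,
monoav_03,mono_plus_avastin,Topotecan,MR,,,yes,responder,
combi_01,combination,Carboplatin,ER,Paclitaxel,ER,no,non_responder,0
combi_02,combination,Carboplatin,MR,Caelyx,ER,no,non_responder,1
combi_03,combination,Carboplatin,ER,Gemcitabine,ER,no,non_responder,0
combi_04,combination,Carboplatin,SR,Paclitaxel,SR,no,non_responder,4
combi_05,combination,Carboplatin,ER,Gemcitabine,ER,no,non_responder,0
combi_06,combination,Carboplatin,ER,Paclitaxel,SR,no,non_responder,2
combi_07,combination,Carboplatin,MR,Caelyx,ER,no,non_responder,1
combi_08,combination,Carboplatin,MR,Paclitaxel,ER,no,non_responder,1
combi_09,combination,Carboplatin,SR,Caelyx,SR,no,responder,4
combi_10,combination,Carboplatin,SR,Gemcitabine,SR,no,responder,4
combi_11,combination,Carboplatin,SR,Paclitaxel,SR,no,responder,4
combi_12,combination,Carboplatin,SR,Caelyx,ER,no,responder,2
combi_13,combination,Carboplatin,SR,Caelyx,ER,no,responder,2
combi_14,combination,Carboplatin,SR,Caelyx,MR,no,responder,3
combi_15,combination,Carboplatin,SR,Caelyx,SR,no,responder,4
combi_16,combination,Carboplatin,MR,Paclitaxel,ER,no,responder,1
combi_17,combination,Carboplatin,SR,Paclitaxel,MR,no,responder,3
combi_18,combination,Carboplatin,MR,Caelyx,SR,no,responder,3
combi_19,combination,Carboplatin,SR,Caelyx,SR,no,responder,4
combi_20,combination,Carboplatin,SR,Paclitaxel,MR,no,responder,3
combi_21,combination,Carboplatin,SR,Caelyx,MR,no,responder,3
combi_22,combination,Carboplatin,ER,Gemcitabine,SR,no,responder,2
combi_23,combination,Carboplatin,SR,Paclitaxel,SR,no,responder,4
combi_24,combination,Carboplatin,MR,Caelyx,MR,no,responder,2
combi_25,combination,Carboplatin,SR,Paclitaxel,MR,no,responder,3
combi_26,combination,Carboplatin,MR,Caelyx,MR,no,responder,2
combi_27,combination,Carboplatin,SR,Caelyx,MR,no,responder,3
combi_28,combination,Carboplatin,SR,Paclitaxel,MR,no,responder,3
combi_29,combination,Carboplatin,SR,Paclitaxel,MR,no,responder,3
combi_30,combination,Carboplatin,SR,Paclitaxel,SR,no,responder,4
combi_31,combination,Carboplatin,SR,Paclitaxel,SR,no,responder,4
combi_32,combination,Carboplatin,ER,Paclitaxel,SR,no,responder,2
combi_33,combination,Carboplatin,SR,Caelyx,SR,no,responder,4
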