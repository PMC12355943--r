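compound,report_no,design,ld50_48h_ug_bee,ld50_10d_ug_bee_day,lc50_chronic_mg_kg,test_duration_d,feeding_duration_h
Deltamethrin,M-149494,acute_contact,0.262,NA,NA,2,NA
Deltamethrin,M-444971,acute_contact,0.119,NA,NA,2,NA
Deltamethrin,M-149496,acute_oral,1.45,NA,NA,2,6
Deltamethrin,M-444971,acute_oral,0.164,NA,NA,2,6
Deltamethrin,M-477250,chronic_oral,NA,0.648,18.0,10,NA
Ethiprole,M-192387,acute_contact,0.0127,NA,NA,2,NA
Ethiprole,M-214951,acute_contact,0.0540,NA,NA,2,NA
Ethiprole,M-192387,acute_oral,0.0336,NA,NA,2,6
Ethiprole,M-214951,acute_oral,0.0327,NA,NA,2,6
Ethiprole,M-581904,chronic_oral,NA,0.000695,0.0478,10,NA
Imidacloprid,M-006940,acute_contact,0.0819,NA,NA,2,NA
Imidacloprid,M-067751,acute_contact,0.0445,NA,NA,2,NA
Imidacloprid,M-068023,acute_contact,0.0728,NA,NA,2,NA
Imidacloprid,M-006940,acute_oral,0.00348,NA,NA,2,6
Imidacloprid,M-016942,acute_oral,0.0763,NA,NA,2,6
Imidacloprid,M-067751,acute_oral,0.0945,NA,NA,2,6
Imidacloprid,M-067996,acute_oral,0.136,NA,NA,2,6
Imidacloprid,M-068023,acute_oral,0.102,NA,NA,2,6
Imidacloprid,M-600686,chronic_oral,NA,0.128,1.32,10,NA
Tetraniliprole,M-438810,acute_contact,0.993,NA,NA,2,NA
Tetraniliprole,M-441758,acute_contact,1.34,NA,NA,2,NA
Tetraniliprole,M-438810,acute_oral,0.106,NA,NA,2,6
Tetraniliprole,M-441758,acute_oral,0.0107,NA,NA,2,6
Tetraniliprole,M-551955,chronic_oral,NA,0.0173,0.710,10,NA
Thiacloprid,M-000856,acute_contact,40.7,NA,NA,2,NA
Thiacloprid,M-001004,acute_contact,44.2,NA,NA,2,NA
Thiacloprid,M-000856,acute_oral,17.5,NA,NA,2,6
Thiacloprid,M-001004,acute_oral,13.7,NA,NA,2,6
Thiacloprid,M-475374,chronic_oral,NA,2.99,48.9,10,NA
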