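exam_id,sex,age_years,weight_kg,height_cm,ap_mm,lat_mm,topogram_length_mm,scan_length_mm,ctdi_vol_mGy,dlp_mGycm,region,phantom,exclusion_flags
ex-001,female,64,69.2,162.1,238.5,348.2,478,455,11.6,528.0,abdomen_pelvis,body32,
ex-002,male,58,79.7,176.8,242.1,352.7,495,490,11.2,548.8,abdomen_pelvis,body32,
ex-003,female,71,58.4,158.0,215.0,322.4,462,440,9.8,431.2,abdomen_pelvis,body32,
ex-004,male,49,95.3,181.5,287.9,401.3,505,512,16.4,839.7,abdomen_pelvis,body32,
ex-005,female,66,72.0,165.5,250.6,355.1,470,470,12.1,568.7,abdomen_pelvis,body32,
ex-006,male,62,84.1,178.2,260.2,368.9,500,478,13.0,621.4,abdomen_pelvis,body32,
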