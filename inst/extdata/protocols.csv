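name,modality,kVp,mAs,fov_length_mm,scan_angle_deg,projections
msct,MSCT,120,54,160,360,
cbct_hires_12x8,CBCT,110,59,80,360,
cbct_standard_15x12,CBCT,110,5.3,120,360,
cbct_standard_18x16,CBCT,110,2.3,160,360,
cbct_verity,CBCT,90,48,160,210,
radiography_ap_lat,radiography,57,16,160,,AP;LAT
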