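name,abbreviation,formula,n_carbons,formula_no_backbone
glu_12345,glu,C19H40NO4Si2,5,C14H40NO4Si2
asp_1234,asp,C18H40NO4Si2,4,C14H40NO4Si2
ala_123,ala,C11H26NOSi,3,C8H26NOSi
suc_1234,suc,C12H23O4Si,4,C8H23O4Si
cit_12345,citf,C26H55O7Si3,5,C21H55O7Si3
pyr_123,pyr,C3H3O3,3,H3O3
co2_1,co2,CO2,1,O2
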