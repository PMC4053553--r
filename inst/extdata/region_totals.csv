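condition,admissions,person_years
diabetes,1490,13131836
copd,20357,13131836
chf,11680,13131836
dehydration,512,13131836
angina,3141,13131836
asthma,2790,13131836
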