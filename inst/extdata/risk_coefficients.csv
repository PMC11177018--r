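# Lifetime attributable risk of thyroid-cancer incidence, cases per 100,000
# persons exposed to a single dose of 0.1 Gy, by sex and age at exposure.
# Provenance: transcribed from BEIR VII (National Research Council, 2006),
# "Health Risks from Exposure to Low Levels of Ionizing Radiation",
# Table 12D-1 (thyroid row). Version 1.
sex,age_at_exposure,lar_per_100k_per_0.1Gy
male,0,115
male,5,76
male,10,50
male,15,33
male,20,21
male,30,9
male,40,3
male,50,1
male,60,0.3
male,70,0.1
male,80,0
female,0,634
female,5,419
female,10,275
female,15,178
female,20,113
female,30,41
female,40,12
female,50,3
female,60,0.7
female,70,0.2
female,80,0
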