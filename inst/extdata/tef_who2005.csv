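# WHO 2005 toxic equivalency factors for the 17 laterally (2,3,7,8-)
# substituted PCDD/F congeners. Source: Van den Berg M. et al. (2006),
# "The 2005 World Health Organization Reevaluation of Human and Mammalian
# Toxic Equivalency Factors for Dioxins and Dioxin-Like Compounds",
# Toxicological Sciences 93(2):223-241.
congener,tef
tcdd_2378,1
pecdd_12378,1
hxcdd_123478,0.1
hxcdd_123678,0.1
hxcdd_123789,0.1
hpcdd_1234678,0.01
ocdd,0.0003
tcdf_2378,0.1
pecdf_12378,0.03
pecdf_23478,0.3
hxcdf_123478,0.1
hxcdf_123678,0.1
hxcdf_123789,0.1
hxcdf_234678,0.1
hpcdf_1234678,0.01
hpcdf_1234789,0.01
ocdf,0.0003
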