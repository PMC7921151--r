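# Proportion (%) of cancers at each site attributable to HPV, by type group,
# from published US CDC genotyping data (2008-2010). Single-sex sites leave sex blank.
site,sex,pct_any_hpv,pct_hpv_16_18,pct_hpv_31_33_45_52_58
cervix,,90.6,66.2,14.7
vagina,,75.0,55.1,18.3
vulva,,68.8,48.6,14.2
penis,,63.3,47.9,9.0
anus,female,92.5,79.5,10.8
anus,male,88.7,79.1,3.8
oropharynx,female,63.3,50.8,9.5
oropharynx,male,72.4,63.4,4.4
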