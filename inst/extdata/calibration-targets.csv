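group,endpoint,value,units
CONT,sfr_force_pct,116.8,%
MCT,sfr_force_pct,141.0,%
CONT,sfr_cat_pct,90.6,%
MCT,sfr_cat_pct,104.3,%
CONT,prp_force_pct,297,%
MCT,prp_force_pct,269,%
CONT,prp_cat_pct,118.7,%
MCT,prp_cat_pct,109.5,%
MCT_vs_CONT,force_ttp_excess_pct,21.5,%
MCT_vs_CONT,cat_ttp_excess_pct,42.6,%
MCT_vs_CONT,cat_ttp_prolong_ms,14.2,ms
MCT_vs_CONT,cat_t50_prolong_ms,9.1,ms
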