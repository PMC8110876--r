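theme,count_top,count_other,pct_top_printed,pct_other_printed,p_printed
health_effects,117530,71167,55.4,49.2,<0.001
pharma,35821,27346,16.9,18.9,<0.001
research,32819,8097,15.5,5.6,<0.001
policy,31723,25621,15.0,17.7,<0.001
ingredients,29281,24858,13.8,17.2,<0.001
family,15508,10628,7.3,7.4,0.68
disease_prevalence,10885,4579,5.1,3.2,<0.001
school,7733,3997,3.6,2.8,<0.001
religion,6884,3343,3.2,2.3,<0.001
natural_alternatives,1953,2287,0.9,1.6,<0.001
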