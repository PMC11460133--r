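currency,factor_per_nzd,reference_year
NZD,1,2019
AUD,1,2019
GBP,0.474072736302533,2019
EUR,0.55,2019
USD,0.68,2019
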