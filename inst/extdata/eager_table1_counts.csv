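variable,level,nonadherent,adherent
treatment,aspirin,190,425
treatment,placebo,179,433
outcome,pregnant,107,677
outcome,not_pregnant,262,181
white,yes,334,827
white,no,35,31
hs_education,yes,302,755
hs_education,no,67,103
married,yes,312,811
married,no,57,47
employed,yes,283,636
employed,no,86,222
income_ge_40k,yes,213,608
income_ge_40k,no,156,250
exercise,low,106,216
exercise,moderate,140,360
exercise,high,123,282
prior_losses,1,125,278
prior_losses,2,244,580
prior_live_births,0,173,352
prior_live_births,1,125,308
prior_live_births,2,68,179
prior_live_births,3,3,19
alcohol_past_year,yes,137,271
alcohol_past_year,no,232,587
smoked_past_year,yes,71,81
smoked_past_year,no,298,777
bleeding,yes,67,166
bleeding,no,302,692
nausea,yes,69,138
nausea,no,300,720
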