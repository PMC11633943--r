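rule_id,label,n,sensitivity,specificity,accuracy,ppv,npv
hypoglycemia,Hypoglycemia (<=70 mg/dL),16,1,1,1,1,1
vte_chemical,Consider chemical VTE prophylaxis,33,1,0.966,0.97,0.8,1
vte_mechanical,Consider mechanical VTE prophylaxis,22,1,1,1,1,1
vte_any,Consider mechanical and/or chemical VTE prophylaxis,33,1,0.962,0.97,0.875,1
sup_start,Consider SUP,18,1,1,1,1,1
sup_stop,Consider to discontinue SUP,9,1,1,1,1,1
low_tidal_volume,Low tidal volume (Vt <=8 mLs/kg),37,1,1,1,1,1
sedation_wean,Ready for sedation wean,115,0.985,0.939,0.965,0.956,0.979
sbt_ready,Ready for Spontaneous Breathing Trial,16,1,1,1,1,1
sbt_passed,Passed Spontaneous Breathing Trial: consider extubation,39,1,1,1,1,1
nutrition_start,Needs nutrition started,46,0.714,0.938,0.87,0.833,0.882
nutrition_adequacy,Not meeting nutritional 80% of need,53,1,0.973,0.981,0.941,1
urinary_catheter_removal,Urinary catheter ready for removal,130,1,0.944,0.985,0.979,1
central_line_removal,Central line ready for removal,149,0.944,0.974,0.96,0.971,0.949
arterial_line_removal,Arterial line ready for removal,189,0.972,0.983,0.979,0.972,0.983
picc_removal,PICC line ready for removal,109,0.974,1,0.991,1,0.986
surveillance_culture,Pre-existing line of admit needs surveillance blood culture,25,NaN,1,1,NaN,1
rectal_tube_removal,Rectal tube ready for removal,66,1,1,1,1,1
ng_to_og,Change Nasogastric tube to an Oralgastric Tube,34,1,1,1,1,1
high_risk_central_line,High risk Central Venous Catheter,84,1,1,1,1,1
high_risk_arterial_line,High risk arterial line,58,1,0.968,0.983,0.964,1
high_risk_hd_line,High risk Hemodialysis line,36,1,0.962,0.972,0.909,1
high_risk_picc,High risk PICC line,67,1,0.967,0.97,0.778,1
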