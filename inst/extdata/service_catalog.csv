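service,cost_initial,cost_low,cost_intermediate,billable_initial,billable_low,billable_intermediate
Consultation,51.01,51.01,51.01,TRUE,TRUE,TRUE
Gynecologic examination,24.75,24.75,24.75,TRUE,TRUE,TRUE
Preliminary discussion for diagnostic/therapeutic interventions,,,29.15,,,TRUE
Special gynecologic counseling,,,29.15,,,TRUE
Informal report (11-35 lines),,,32.05,,,TRUE
Document review (patient not present; 18 min),,,52.44,,,TRUE
Blood pressure measurement,19.60,19.60,,TRUE,TRUE,
Venipuncture for blood withdrawal,6.42,6.42,6.42,FALSE,FALSE,TRUE
Proteinuria (fast strip),,4.58,,,TRUE,
Proteinuria (quantitative),141.86,,,TRUE,,
Urine part status (5-10 parameter),,,0.88,,,TRUE
Thrombocyte; hemoglobin; hematocrit,7.92,,,TRUE,,
ALAT/GPT,2.20,,2.20,TRUE,,TRUE
ASAT/GOT,6.95,,2.20,TRUE,,TRUE
LDH,2.20,,2.20,TRUE,,TRUE
Bilirubin,6.95,,,TRUE,,
Urate,6.95,,,TRUE,,
Creatinine,6.95,,2.20,TRUE,,TRUE
Haptoglobin,17.51,,17.51,TRUE,,TRUE
Blood coagulation test,25.08,,,TRUE,,
Sonography (with fetal Doppler),58.36,58.36,58.36,TRUE,TRUE,TRUE
Ultrasound examination,79.06,79.06,151.95,TRUE,TRUE,TRUE
CTG,66.83,22.28,66.83,TRUE,TRUE,TRUE
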