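drug_id,ingredient,amount,amount_unit,volume_ml,standard_unit,rate_min,rate_max,bolus_min,bolus_max
D001,norepinephrine,5,mg,50,mg/h,0.1,5,0.005,0.1
D002,epinephrine,5,mg,50,mg/h,0.05,2,0.01,0.1
D003,propofol,1000,mg,50,mg/h,50,300,20,200
D004,sufentanil,0.25,mg,50,mg/h,0.01,0.1,0.005,0.05
D005,midazolam,90,mg,45,mg/h,2,20,1,5
D006,heparin,25000,U,50,U/h,500,2000,1000,5000
D007,insulin_aspart,50,U,50,U/h,0.5,10,2,10
D008,furosemide,250,mg,50,mg/h,1,20,10,40
D009,vasopressin,40,U,40,U/h,1,4,0.5,2
D010,dexmedetomidine,0.4,mg,50,mg/h,0.02,0.14,0.01,0.05
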