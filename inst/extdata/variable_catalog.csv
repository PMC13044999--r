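variable_id,name,unit,lower,upper,poc
HR,heart_rate,/min,0,300,0
MAP,mean_arterial_pressure,mmHg,0,250,0
SPO2,spo2,%,0,100,0
TEMP,temperature,degC,20,45,0
LACT,lactate,mmol/L,0,30,1
PH,ph,pH,6.5,8,1
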