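department,temp_mean,temp_max,temp_min,insolation,daylength,rainfall,days_rain
Cesar,21.6,27.8,16.5,75039,2214,1090,70
Caldas,21.1,28.4,16.9,75921,2213,1520,108
Quindio,21.9,29.5,17.4,75978,2213,1265,82
Cauca,19.1,26.3,14.5,76120,2212,1075,88
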