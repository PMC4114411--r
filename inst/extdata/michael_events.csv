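episode_id,timestamp,entity,state
michael_f1_e001,1,Alarm,on
michael_f1_e001,2,Bathroom,on
michael_f1_e001,3,Bathroom,off
michael_f1_e001,4,Kitchen,on
michael_f1_e001,5,Breakfast,on
michael_f1_e001,6,Pill,on
michael_f1_e001,7,Kitchen,off
michael_f1_e002,1,Alarm,on
michael_f1_e002,2,Bathroom,on
michael_f1_e002,3,Shower,on
michael_f1_e002,4,Shower,off
michael_f1_e002,5,Bathroom,off
michael_f1_e002,6,Kitchen,on
michael_f1_e002,7,Breakfast,on
michael_f1_e002,8,Pill,on
michael_f1_e002,9,Kitchen,off
michael_f1_e003,1,Alarm,on
michael_f1_e003,2,Bathroom,on
michael_f1_e003,3,Shower,on
michael_f1_e003,4,Shower,off
michael_f1_e003,5,Bathroom,off
michael_f1_e003,6,Kitchen,on
michael_f1_e003,7,Breakfast,on
michael_f1_e003,8,Pill,on
michael_f1_e003,9,Kitchen,off
michael_f1_e004,1,Alarm,on
michael_f1_e004,2,Bathroom,on
michael_f1_e004,3,Shower,on
michael_f1_e004,4,Shower,off
michael_f1_e004,5,Bathroom,off
michael_f1_e004,6,Kitchen,on
michael_f1_e004,7,Breakfast,on
michael_f1_e004,8,Pill,on
michael_f1_e004,9,Kitchen,off
michael_f1_e005,1,Alarm,on
michael_f1_e005,2,Bathroom,on
michael_f1_e005,3,Shower,on
michael_f1_e005,4,Shower,off
michael_f1_e005,5,Bathroom,off
michael_f1_e005,6,Kitchen,on
michael_f1_e005,7,Breakfast,on
michael_f1_e005,8,Pill,on
michael_f1_e005,9,Kitchen,off
michael_f1_e006,1,Alarm,on
michael_f1_e006,2,Bathroom,on
michael_f1_e006,3,Shower,on
michael_f1_e006,4,Shower,off
michael_f1_e006,5,Bathroom,off
michael_f1_e006,6,Kitchen,on
michael_f1_e006,7,Breakfast,on
michael_f1_e006,8,Pill,on
michael_f1_e006,9,Kitchen,off
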