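vehicle_id,t_start_iso,duration_h,mean_speed_kmh,path_length_km
veh-A,2011-05-01T08:00:00,0.1666667,5.4,0.9
veh-A,2011-05-01T09:00:00,0.0666667,22.5,1.5
veh-A,2011-05-01T10:00:00,0.1666667,12.0,2.0
veh-B,2011-05-01T08:30:00,0.1666667,6.0,1.0
veh-B,2011-05-01T09:30:00,0.08,62.5,5.0
veh-B,2011-05-01T11:00:00,0.5,20.0,10.0
veh-C,2011-05-01T12:00:00,0.1,12.0,1.2
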