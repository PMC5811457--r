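individual_id,clone,treatment,chemostat_replicate,event_type,event_time_h,egg_index
LP.R1.I01,D12,LP,R1,hatch,0,
LP.R1.I01,D12,LP,R1,egg_laid,20,1
LP.R1.I01,D12,LP,R1,egg_laid,26,2
LP.R1.I01,D12,LP,R1,egg_hatched,32,1
LP.R1.I01,D12,LP,R1,egg_laid,32,3
LP.R1.I01,D12,LP,R1,egg_laid,38,4
LP.R1.I01,D12,LP,R1,egg_died,40,2
LP.R1.I01,D12,LP,R1,egg_hatched,44,3
LP.R1.I01,D12,LP,R1,egg_laid,44,5
LP.R1.I01,D12,LP,R1,egg_hatched,50,4
LP.R1.I01,D12,LP,R1,egg_hatched,56,5
LP.R1.I01,D12,LP,R1,censored,62,
LP.R1.I02,D12,LP,R1,hatch,0,
LP.R1.I02,D12,LP,R1,egg_laid,22,1
LP.R1.I02,D12,LP,R1,egg_laid,30,2
LP.R1.I02,D12,LP,R1,egg_hatched,34,1
LP.R1.I02,D12,LP,R1,egg_laid,38,3
LP.R1.I02,D12,LP,R1,egg_hatched,42,2
LP.R1.I02,D12,LP,R1,egg_laid,46,4
LP.R1.I02,D12,LP,R1,egg_died,52,3
LP.R1.I02,D12,LP,R1,egg_laid,54,5
LP.R1.I02,D12,LP,R1,egg_hatched,58,4
LP.R1.I02,D12,LP,R1,censored,62,
LP.R1.I03,D12,LP,R1,hatch,0,
LP.R1.I03,D12,LP,R1,egg_laid,24,1
LP.R1.I03,D12,LP,R1,egg_laid,32,2
LP.R1.I03,D12,LP,R1,egg_died,38,1
LP.R1.I03,D12,LP,R1,egg_laid,40,3
LP.R1.I03,D12,LP,R1,egg_hatched,44,2
LP.R1.I03,D12,LP,R1,egg_laid,48,4
LP.R1.I03,D12,LP,R1,egg_hatched,52,3
LP.R1.I03,D12,LP,R1,egg_hatched,60,4
LP.R1.I03,D12,LP,R1,censored,62,
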