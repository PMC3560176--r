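task,trial_index,onset_ms,stimulus_code,is_target,responded,rt_ms
no4s,1,0,16,TRUE,TRUE,405
no4s,2,3000,8,TRUE,TRUE,415
no4s,3,6000,5,TRUE,TRUE,425
no4s,4,9000,16,TRUE,TRUE,435
no4s,5,12000,8,TRUE,FALSE,
no4s,6,15000,4,FALSE,TRUE,350
no4s,7,18000,16,TRUE,TRUE,445
no4s,8,21000,5,TRUE,TRUE,455
no4s,9,24000,8,TRUE,TRUE,465
no4s,10,27000,16,TRUE,TRUE,475
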