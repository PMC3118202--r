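id,arm,time_days,status
1,1,51,1
1,1,185,1
1,1,413,1
1,1,692,0
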