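dimension,level,count
strength,First class,33
strength,Second class,38
strength,Third class,152
strength,Fourth class,135
strength,Fifth class,374
ownership,Private,376
ownership,Public,356
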