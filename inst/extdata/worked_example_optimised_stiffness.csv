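load_type,dof,initial,s1,s2,s3,s4,s5,s6
lb,lb,68.8,107.0,63.0,77.8,105.5,68.8,87.5
lb,ar,291,291.0,270.4,293.8,289.7,291.1,291.5
lb,fe,51,49.5,68.0,50.7,50.1,51.0,65.1
ar,lb,68.8,93.3,NA,99.0,101.3,94.9,NA
ar,ar,291,295.1,NA,282.7,418.7,310.9,NA
ar,fe,51,58.5,NA,47.2,143.8,18.0,NA
fe,lb,68.8,69.4,79.8,67.3,70.5,59.1,68.6
fe,ar,291,291.1,296.4,291.0,291.3,292.7,291.7
fe,fe,51,61.9,65.2,60.5,79,94.2,102.2
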