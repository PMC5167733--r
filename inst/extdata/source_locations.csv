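node,mni_x,mni_y,mni_z,t_value
SIc,-57,-19,49,9.8
SIIc,-48,-28,16,10.5
SIIi,51,-25,19,10.2
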