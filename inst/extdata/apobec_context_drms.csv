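gene,position,aa
RT,67,N
RT,138,K
RT,184,I
RT,190,E
RT,190,S
RT,230,I
IN,118,R
IN,138,K
IN,140,R
IN,140,S
IN,163,K
IN,163,R
IN,232,N
IN,263,K
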