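gene,position,aa
RT,16,K
RT,25,N
RT,40,K
RT,73,K
RT,88,N
RT,112,N
RT,126,K
RT,150,K
RT,165,K
RT,177,N
RT,198,K
RT,211,K
RT,219,N
RT,237,K
IN,11,N
IN,17,K
IN,45,K
IN,59,N
IN,79,K
IN,93,N
IN,112,K
IN,128,K
IN,151,N
IN,171,K
IN,188,N
IN,211,K
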