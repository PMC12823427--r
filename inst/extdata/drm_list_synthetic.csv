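gene,position,aa,drug
RT,101,E,rilpivirine
RT,101,P,rilpivirine
RT,108,I,rilpivirine
RT,138,A,rilpivirine
RT,138,G,rilpivirine
RT,138,K,rilpivirine
RT,138,Q,rilpivirine
RT,181,C,rilpivirine
RT,181,I,rilpivirine
RT,188,L,rilpivirine
RT,227,C,rilpivirine
RT,230,I,rilpivirine
RT,230,L,rilpivirine
IN,92,V,cabotegravir
IN,118,R,cabotegravir
IN,138,K,cabotegravir
IN,140,R,cabotegravir
IN,140,S,cabotegravir
IN,148,H,cabotegravir
IN,148,K,cabotegravir
IN,148,R,cabotegravir
IN,155,H,cabotegravir
IN,263,K,cabotegravir
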