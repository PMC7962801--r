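(P:1.0,(((EI:0.2,LI:0.2):0.35,((C:0.2,G:0.2):0.15,VG:0.35):0.2):0.2,(EE:0.25,LE:0.25):0.5):0.25);
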