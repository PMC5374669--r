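((((L1:0.6,L2:0.8):0.5,(L3:0.7,L4:0.6):0.6):0.5,((L5:0.9,L6:0.7):0.6,L7:1.0):0.4):0.5,((L8:0.8,L9:0.9):0.7,(L10:0.6,L11:0.8):0.5):0.6);
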