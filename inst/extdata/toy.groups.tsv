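T01	Target
T02	Target
T03	Target
C01	Control
C02	Control
C03	Control
B01	Background
B02	Background
B03	Background
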