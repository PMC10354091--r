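SYNPZ001
SYNPZ002
SYNPZ003
SYNPZ004
SYNPZ005
SYNPZ006
SYNPZ007
SYNSH001
SYNSH002
SYNSH003
SYNSH004
SYNSH005
SYNSH006
SYNSH007
SYNSH008
SYNSH009
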