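SYNAO001
SYNAO002
SYNAO003
SYNAO004
SYNAO005
SYNAO006
SYNAO007
SYNAO008
SYNAO009
SYNAO010
SYNAO011
SYNAO012
SYNAO013
SYNAO014
SYNAO015
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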