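id	type
CrtE_typeIII_synthetic	III
HsGGPPS_typeIII_synthetic	III
RtGGPPS_typeIII_synthetic	III
ScGGPPS_typeIII_synthetic	III
CfGGPPS_typeIII_synthetic	III
AtGGPPS_typeII_synthetic	II
PaGGPPS_typeII_synthetic	II
GaGGPPS_typeI_synthetic	I
PhGGPPS_typeI_synthetic	I
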