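rsid	confounder_trait	source
rs1800562	diabetes	synthetic example
rs7903146	diabetes	synthetic example
rs738409	cholestasis	synthetic example
rs58542926	cholestasis	synthetic example
rs1229984	alcohol use	synthetic example
rs671	alcohol use	synthetic example
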