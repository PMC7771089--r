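FOLATE_METABOLISM_SYNTHETIC	synthetic:PID-like	G0001	G0002	G0003	G0004	G0005	G0006
FOLATE_METABOLISM_SYNTHETIC	synthetic:PANTHER-like	G0001	G0002	G0003	G0004	G0007
PURINE_SYNTHESIS_SYNTHETIC	synthetic:INOH-like	G0011	G0012	G0013	G0014	G0015
GLYCOLYSIS_SYNTHETIC	synthetic:PID-like	G0021	G0022	G0023	G0024
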