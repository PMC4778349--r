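GUACUAUU
UGUUCUAU
GUUUAUAU
GUGAGUUU
GUUGCAUU
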