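# example targets: SMILES<whitespace>ID
CCOC(=O)C ethyl_acetate
Cc1ccc(O)cc1 p_cresol
CCCCCC hexane
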