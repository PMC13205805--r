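depth,category,median_days
superficial,<=9,26
superficial,10-18,63
superficial,>=19,259
deep,<=9,26
deep,10-18,63
deep,>=19,259
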