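casrn	name
14797-73-0	perchlorate
14797-55-8	nitrate
14265-44-2	phosphate
14808-79-8	sulfate
57-12-5	cyanide ion
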