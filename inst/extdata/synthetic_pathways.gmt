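focal_adhesion	synthetic	P00001	P00002	P00003	P00004
nuclear_envelope	synthetic	P00002	P00003	P00004	P00005
tiny_set	synthetic	P00001	P00002
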