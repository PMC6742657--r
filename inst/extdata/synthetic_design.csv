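sample_id,group,donor
control_D1,control,D1
control_D2,control,D2
control_D3,control,D3
strain_0h_D1,strain_0h,D1
strain_0h_D2,strain_0h,D2
strain_0h_D3,strain_0h,D3
strain_24h_D1,strain_24h,D1
strain_24h_D2,strain_24h,D2
strain_24h_D3,strain_24h,D3
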