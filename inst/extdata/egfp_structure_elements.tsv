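name	kind	start	end
helix1	alpha_helix	56	72
beta2	beta_strand	31	35
lid_top_G20	lid	20	20
lid_nc_G91	lid	91	91
lid_top_G127	lid	127	127
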