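name,molar_mass_g_mol,antoine_A,antoine_B,antoine_C,T_min_K,T_max_K,gamma_default,liquid_density_kg_m3
propylene_glycol,76.09,11.91889,3185.244,0,278,461,1.0,1036
glycerol,92.09,12.71992,4344.255,0,278,563,1.0,1261
water,18.015,10.19621,1730.63,-39.724,274,373,1.0,997
nicotine,162.23,10.78165,3004.35,0,278,520,1.0,1010
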