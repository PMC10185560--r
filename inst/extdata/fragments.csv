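analyte,mz,carbon_sources
glycine,218,methylene_HCHO
glycine,246,carboxyl_CO2;methylene_HCHO
serine,288,carboxyl_CO2;methylene_HCHO
serine,302,methylene_HCHO;beta_THF
serine,390,carboxyl_CO2;methylene_HCHO;beta_THF
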