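id,name,step_ids,description
P1,reductive glycine pathway (formate),for_act;fthf_red;rgcs_nadh,Formate activated to formyl-THF and reduced to methylene-THF feeding the NADH-coupled rGCS
P2,formate via formaldehyde,for_red;hcho_thf;rgcs_nadh,Formate reduced to formaldehyde then condensed with THF; NADH-coupled rGCS
P3,formate via formyl phosphate,fp_form;fp_red;hcho_thf;rgcs_nadh,Formate routed through formyl phosphate to formaldehyde; NADH-coupled rGCS
P4,formate reduction route (DTT rGCS),for_red;hcho_thf;rgcs_dtt,Direct formate reduction to formaldehyde (large barrier) feeding the DTT-driven rGCS
P5,methanol dehydrogenation route (DTT rGCS),mdh;hcho_thf;rgcs_dtt,NAD-dependent methanol dehydrogenation (large barrier) feeding the DTT-driven rGCS
P6,methanol oxidase route (DTT rGCS),aox;hcho_thf;rgcs_dtt,Alcohol-oxidase methanol oxidation with spontaneous formaldehyde-THF condensation and the DTT-driven rGCS
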