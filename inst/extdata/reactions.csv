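id,name,equation,ref_energy_kj_mol,ref_ph,ref_ionic_strength,source
for_act,formate activation to 10-formyl-THF,formate + THF + ATP = formylTHF + ADP + Pi,,7.5,0.20,user
fthf_red,formyl-THF reduction to methylene-THF,formylTHF + NADPH = CH2THF + NADP,,7.5,0.20,user
for_red,formate reduction to formaldehyde,formate + NADH = HCHO + NAD,,7.5,0.20,user
fp_form,formyl phosphate formation,formate + ATP = formylP + ADP,,7.5,0.20,user
fp_red,formyl phosphate reduction to formaldehyde,formylP + NADH = HCHO + NAD + Pi,,7.5,0.20,user
mdh,methanol dehydrogenation (NAD-dependent),methanol + NAD = HCHO + NADH,,7.5,0.20,user
aox,methanol oxidation (alcohol oxidase),methanol + O2 = HCHO + H2O2,,7.5,0.20,user
hcho_thf,formaldehyde-THF condensation,HCHO + THF = CH2THF,,7.5,0.20,user
rgcs_nadh,rGCS glycine synthesis (NADH),CO2 + CH2THF + NH3 + NADH = glycine + THF + NAD,-1.2,7.5,0.20,reference
lip_nadh,lipoamide reduction by NADH (L protein),Hox + NADH = Hred + NAD,-0.6,7.5,0.20,reference
lip_dtt,lipoamide reduction by DTT,Hox + DTT = Hred + DTTox,-7.4,7.5,0.20,reference
lip_tcep,lipoamide reduction by TCEP,Hox + TCEP + H2O = Hred + TCEPO,,7.5,0.20,user
rgcs_core,rGCS excluding carrier re-reduction,CO2 + CH2THF + NH3 + Hred = glycine + THF + Hox,-0.6,7.5,0.20,derived
rgcs_dtt,rGCS glycine synthesis (DTT),CO2 + CH2THF + NH3 + DTT = glycine + THF + DTTox,-8.0,7.5,0.20,reference
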