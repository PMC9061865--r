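# Published Arrhenius constants (prefactor A, activation energy Ea) derived
# from the per-temperature release parameters of the BR and BRD reference
# tables. The BR k_r prefactor is printed inconsistently between the source
# table (4321997.7158, canonical: back-calculation from k_r(37 degC) and
# E_ar supports it) and a figure caption (4921997.7158); both are retained.
model,parameter,constant,unit,value,source,canonical
br,k_b,prefactor,day^-1,1703.0412,table,TRUE
br,k_b,ea_kcal,kcal mol^-1,4.2211,table,TRUE
br,k_r,prefactor,day^-1,4321997.7158,table,TRUE
br,k_r,prefactor,day^-1,4921997.7158,figure_caption,FALSE
br,k_r,ea_kcal,kcal mol^-1,10.7711,table,TRUE
br,t_max,prefactor,day,3.3883e-9,table,TRUE
br,t_max,ea_kcal,kcal mol^-1,-13.8709,table,TRUE
brd,k_b,prefactor,day^-1,182668.5606,table,TRUE
brd,k_b,ea_kcal,kcal mol^-1,6.8957,table,TRUE
brd,k_r,prefactor,day^-1,7.22680605824739e30,table,TRUE
brd,k_r,ea_kcal,kcal mol^-1,45.0589,table,TRUE
brd,t_max,prefactor,day,1.3220e-7,table,TRUE
brd,t_max,ea_kcal,kcal mol^-1,-11.7986,table,TRUE
brd,D_e,prefactor,cm^2 s^-1,3.3345e-11,table,TRUE
brd,D_e,ea_kcal,kcal mol^-1,9.9030,table,TRUE
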