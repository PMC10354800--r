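# Reference validation set: 22 e-liquids (4 commercial NJOY pods, 18 lab-made
# nicotine salts) with apparent pH, PG/VG composition, dielectric constant,
# and the freebase / monoprotonated results from both the pH method and the
# liquid-liquid extraction (LLE) reference method.
# mp_ph / mp_lle are fractions for the commercial rows and mg/mL for the
# lab-made rows (the original reporting convention).
label,nicotine_conc,vol_pct_pg,vol_pct_vg,dielectric,ph_app,fb_ph,fb_lle,mp_ph,mp_lle,pct_difference
NJOY Ace-Classic Tobacco,28,52.33,47.67,34.67,6.06,0.143,0.150,0.857,0.850,0.8
NJOY Ace-Classic Tobacco,58,45.49,54.51,35.69,6.16,0.166,0.090,0.834,0.910,8.4
NJOY Ace-Menthol,28,47.99,52.01,35.32,6.02,0.128,0.121,0.872,0.879,0.8
NJOY Ace-Menthol,58,46.01,53.99,35.62,6.16,0.166,0.103,0.834,0.897,7.0
nicotine lactate,12,100,0,27.50,6.06,0.202,0.178,9.580,9.860,2.8
nicotine lactate,60,100,0,27.50,6.28,0.295,0.244,42.275,45.380,6.8
nicotine lactate,12,70,30,32.02,6.29,0.249,0.237,9.017,9.153,1.5
nicotine lactate,60,70,30,32.02,6.44,0.318,0.268,40.894,43.906,6.9
nicotine lactate,12,30,70,38.02,6.53,0.289,0.293,8.529,8.483,0.5
nicotine lactate,60,30,70,38.02,6.54,0.294,0.244,42.361,45.342,6.6
nicotine salicylate,12,100,0,27.50,5.42,0.055,0.039,11.343,11.535,1.7
nicotine salicylate,60,100,0,27.50,5.22,0.035,0.009,57.886,59.462,2.7
nicotine salicylate,12,70,30,32.02,5.46,0.047,0.031,11.440,11.634,1.7
nicotine salicylate,60,70,30,32.02,5.71,0.080,0.041,55.198,57.525,4.0
nicotine salicylate,12,30,70,38.02,5.58,0.044,0.048,11.476,11.423,0.5
nicotine salicylate,60,30,70,38.02,5.79,0.069,0.046,55.864,57.233,2.4
nicotine benzoate,12,100,0,27.50,6.07,0.205,0.054,9.535,11.352,16.0
nicotine benzoate,60,100,0,27.50,6.22,0.267,0.050,43.950,56.982,22.9
nicotine benzoate,12,70,30,32.02,6.16,0.197,0.070,9.637,11.156,13.6
nicotine benzoate,60,70,30,32.02,6.23,0.224,0.045,46.581,57.306,18.7
nicotine benzoate,12,30,70,38.02,6.09,0.129,0.059,10.455,11.293,7.4
nicotine benzoate,60,30,70,38.02,6.14,0.142,0.070,51.468,55.824,7.8
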