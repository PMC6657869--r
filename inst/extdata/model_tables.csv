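"table","model","K","AIC","delta","w"
2,"Fledglings per clutch",3,362.15,0,0.3
2,"Clutch size",3,362.53,0.38,0.25
2,"Migratory status",3,363.03,0.88,0.19
2,"Fledglings per clutch + migratory status",4,363.76,1.61,0.13
2,"Fledglings per clutch + frugivory",4,363.82,1.67,0.13
3,"Granivory",3,716.48,0,0.27
3,"Cavity nesting + granivory",4,717.6,1.12,0.15
3,"Clutch size + granivory",4,717.65,1.18,0.15
3,"Granivory + migratory status",4,718.14,1.67,0.12
3,"Migratory status",3,718.36,1.88,0.1
3,"Frugivory + Granivory",4,718.36,1.89,0.1
3,"Clutch size",3,718.39,1.91,0.1
4,"Frugivory",3,168.33,0,0.13
4,"Frugivory + granivory",4,168.82,0.49,0.1
4,"Wingspan",3,168.91,0.58,0.1
4,"Clutch size + frugivory",4,168.99,0.66,0.09
4,"Granivory",3,169.23,0.9,0.08
4,"Flock size + frugivory",4,169.41,1.08,0.07
4,"Omnivory",3,169.41,1.08,0.07
4,"Granivory + wingspan",4,169.48,1.15,0.07
4,"Cavity nesting + frugivory",4,169.5,1.17,0.07
4,"Cavity nesting",3,169.88,1.55,0.06
4,"Frugivory + wingspan",4,170.17,1.84,0.05
4,"Flock size + wingspan",4,170.28,1.95,0.05
4,"Omnivory + wingspan",4,170.3,1.97,0.05
5,"Frugivory + granivory",4,369.4,0,0.21
5,"Granivory + omnivory",4,369.43,0.03,0.2
5,"Granivory",3,369.48,0.08,0.2
5,"Omnivory",3,370.04,0.64,0.15
5,"Clutch size + frugivory + granivory",5,371.17,1.77,0.09
5,"Cavity nesting + granivory",4,371.27,1.87,0.08
5,"Frugivory + granivory + omnivory",5,371.38,1.98,0.08
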