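# Sown area, grain yield and national average unit price of the main crops
# of Anyang (2015 statistics as published). The yield column is transcribed
# as printed, labelled 10^4 t; see the package vignette for the unit
# discussion around the regional unit value E.
crop_type,variety,sown_area_hm2,grain_yield_10kt,price_yuan_per_t
Cereals,Wheat,308968,5.84,2413
Cereals,Maize,236884,5.57,1771
Cereals,Sorghum,17000,3.20,2400
Beans,Soybean,5206,2.64,3529
Beans,Miscellaneous beans,464,1.44,3488
Potatoes,Sweet potatoes,8127,6.59,2000
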