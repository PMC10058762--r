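group,low,high,reference
cereals_tubers,250,400,325
vegetables,300,500,400
fruits,200,350,275
meat,40,75,57.5
aquatic_products,40,75,57.5
soybean_nuts,25,35,30
eggs,40,50,45
dairy,300,500,400
edible_oil,25,30,27.5
salt,1,5,3
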