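"sensor_id","object","type","states"
"SM1","Kitchen area","Motion","Movement/No movement"
"SM3","Bathroom area","Motion","Movement/No movement"
"SM4","Bedroom area","Motion","Movement/No movement"
"SM5","Sofa area","Motion","Movement/No movement"
"M01","Door","Contact","Open/Close"
"TV0","TV","Contact","Open/Close"
"D01","Refrigerator","Contact","Open/Close"
"D02","Microwave","Contact","Open/Close"
"D03","Wardrobe","Contact","Open/Close"
"D04","Cups cupboard","Contact","Open/Close"
"D05","Dishwasher","Contact","Open/Close"
"D07","WC","Contact","Open/Close"
"D08","Closet","Contact","Open/Close"
"D09","Washing machine","Contact","Open/Close"
"D10","Pantry","Contact","Open/Close"
"C01","Medication box","Contact","Open/Close"
"C02","Fruit platter","Contact","Open/Close"
"C03","Cutlery","Contact","Open/Close"
"C04","Pots","Contact","Open/Close"
"C05","Water bottle","Contact","Open/Close"
"C07","XBOX Remote","Contact","Present/Not present"
"C08","Trash","Contact","Open/Close"
"C09","Tap","Contact","Open/Close"
"C10","Tank","Contact","Open/Close"
"C12","Laundry basket","Contact","Present/Not present"
"C13","Pyjamas drawer","Contact","Open/Close"
"C14","Bed","Pressure","Pressure/No pressure"
"C15","Kitchen faucet","Contact","Open/Close"
"H01","Kettle","Contact","Open/Close"
"S09","Sofa","Pressure","Pressure/No pressure"
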