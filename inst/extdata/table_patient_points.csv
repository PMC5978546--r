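label,plan,point,reference_dose,clinical1_dose,clinical1_diff_pct,clinical2_dose,clinical2_diff_pct,new_dose,new_diff_pct
conventional_CW1,conventional,CW1,4562.6,4564.9,0.05,4563.2,0.01,4563.5,0.02
conventional_CW2,conventional,CW2,4561.8,4566.5,0.10,4563,0.03,4563.1,0.03
conventional_skin1,conventional,skin1,5336.7,4815.8,-9.76,5161.4,-3.28,4985.8,-6.58
conventional_skin2,conventional,skin2,5213.7,4813,-7.69,5046.6,-3.21,4928.3,-5.47
vmat_CW1,vmat,CW1,4972.2,4968.3,-0.08,4967,-0.10,4951.5,-0.42
vmat_CW2,vmat,CW2,4887.8,4872,-0.32,4875.8,-0.25,4857.4,-0.62
vmat_skin1,vmat,skin1,5090.2,5050.3,-0.78,5070,-0.40,5050.9,-0.77
vmat_skin2,vmat,skin2,5250.2,4892.8,-6.81,5099.1,-2.88,4988.6,-4.98
imrt4_CW1,imrt4,CW1,4972.4,4971.3,-0.02,4973.2,0.02,4973.7,0.03
imrt4_CW2,imrt4,CW2,5021.9,5020.8,-0.02,5024,0.04,5024.8,0.06
imrt4_skin1,imrt4,skin1,5312,4986.7,-6.12,5183.5,-2.42,5119.4,-3.63
imrt4_skin2,imrt4,skin2,5533.9,5205.9,-5.93,5378.7,-2.80,5333,-3.63
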