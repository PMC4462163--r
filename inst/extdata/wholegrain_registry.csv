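food_code,description,food_group,wheat,oats,maize,rice,rye,barley,quinoa,millet,cooking_loss_percent,cooked_form_of
WB001,wholemeal bread (synthetic illustrative record),bread,51,0,0,0,0,0,0,0,0,
WB002,wholemeal toast (cooked form of WB001),bread,0,0,0,0,0,0,0,0,14.6,WB001
RT001,wholewheat biscuit cereal,RTEC,84,0,0,0,0,0,0,0,0,
RT002,multigrain flakes,RTEC,38,22,0,0,0,0,0,0,0,
PO001,porridge made with water,porridge,0,13,0,0,0,0,0,0,0,
PA001,wholewheat pasta boiled,pasta,31,0,0,0,0,0,0,0,0,
RI001,brown rice boiled,rice,0,0,0,32,0,0,0,0,0,
SA001,rye crispbread,savoury_snacks,0,0,0,0,82,0,0,0,0,
SA002,corn tortilla chips,savoury_snacks,0,0,56,0,0,0,0,0,0,
SW001,oat cereal bar,sweet_snacks,9,26,0,0,0,0,0,0,0,
SW002,popcorn,sweet_snacks,0,0,68,0,0,0,0,0,0,
BA001,wholemeal scone,bakes,35,0,0,0,0,0,0,0,0,
OC001,barley and millet cereal mix,other_cereals,0,0,0,0,0,28,0,12,0,
OC002,quinoa boiled,other_cereals,0,0,0,0,0,0,28,0,0,
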