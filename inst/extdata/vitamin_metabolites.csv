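metabolite,vitamin_group,effect
cobalamin,vitamin B12,acceleration
cholecalciferol,vitamin D3,acceleration
ergocalciferol,vitamin D2,acceleration
menaquinone,vitamin K2,inhibition
menadione,vitamin K3,inhibition
retinoic acid,vitamin A,inhibition
alpha-tocopherol,vitamin E,acceleration
4-aminobenzoic acid,vitamin B,no effect
biotin,vitamin B7,no effect
folic acid,vitamin M,no effect
niacinamide,vitamin B3,no effect
d-pantothenic acid hemicalcium salt,vitamin B5,no effect
pyridoxal hydrochloride,vitamin B6 group,no effect
pyridoxamine dihydrochloride,vitamin B6 group,no effect
pyridoxine hydrochloride,vitamin B6 group,no effect
riboflavin,vitamin B2,no effect
thiamine hydrochloride,vitamin B1,no effect
alpha-lipoic acid,vitamin-like antioxidant,no effect
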