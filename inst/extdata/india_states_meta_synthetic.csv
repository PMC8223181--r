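state,has_districts,confirmed_at_cutoff
Andaman and Nicobar Islands,true,33
Andhra Pradesh,true,2407
Arunachal Pradesh,true,1
Assam,true,107
Bihar,true,1391
Chandigarh,false,191
Chhattisgarh,true,86
Dadra and Nagar Haveli and Daman and Diu,true,1
Delhi,true,10054
Goa,true,29
Gujarat,true,11745
Haryana,true,928
Himachal Pradesh,true,90
Jammu and Kashmir,true,1183
Jharkhand,true,223
Karnataka,true,1246
Kerala,true,630
Ladakh,true,43
Lakshadweep,true,0
Madhya Pradesh,true,5236
Maharashtra,true,33053
Manipur,true,7
Meghalaya,true,13
Mizoram,true,1
Nagaland,true,0
Odisha,true,876
Puducherry,true,13
Punjab,true,1964
Rajasthan,true,5507
Sikkim,true,0
Tamil Nadu,true,11760
Telangana,true,1592
Tripura,true,167
Uttar Pradesh,true,4464
Uttarakhand,true,92
West Bengal,true,2825
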