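state,river,alewife_demog,alewife_stock,alewife_priority,blueback_demog,blueback_stock,blueback_priority
ME,Dennys,N,NNE,medium,N,NNE,medium
ME,East Machias,N,NNE,medium,N,NNE,medium
ME,Narraguagus,N,NNE,medium,N,NNE,medium
ME,Union,Y,NNE,low,N,NNE,medium
ME,Orland,N,NNE,medium,N,NNE,medium
ME,Penobscot,N,NNE,medium,N,NNE,medium
ME,Soudabscook,N,NNE,medium,N,NNE,medium
ME,St George,N,NNE,medium,N,NNE,medium
ME,Damariscotta,Y,NNE,medium,N,NNE,medium
ME,Sheepscot,N,NNE,medium,N,NNE,medium
ME,Kennebec,N,NNE,medium,N,NNE,medium
ME,Androscoggin,Y,NNE,medium,N,NNE,medium
ME,Presumpscot,N,NNE,medium,N,NNE,medium
ME,Saco,N,NNE,medium,N,NNE,medium
NH,Cocheco,Y,NNE,medium,Y,NNE,medium
NH,Oyster,N,NNE,medium,Y,NNE,high
NH,Exeter,Y,NNE,medium,N,NNE,medium
NH,Lamprey,Y,NNE,low,N,NNE,medium
NH,Winnicut,Y,NNE,low,Y,NNE,medium
MA,Merrimac,N,SNE,high,N,SNE,high
MA,Parker,Y,SNE,medium,N,SNE,high
MA,Mystic,N,SNE,high,N,SNE,high
MA,Charles,N,SNE,high,N,SNE,high
MA,Stony Brook,Y,SNE,high,N,SNE,high
MA,Town Brook,N,SNE,high,N,SNE,high
MA,Monument,Y,SNE,high,Y,SNE,high
MA,Mattipoisett,Y,SNE,high,N,SNE,high
MA,Nemasket,Y,SNE,high,N,SNE,high
RI,Nonquit,Y,SNE,high,N,SNE,high
RI,Gilbert Stuart,Y,SNE,low,N,SNE,high
CT,Connecticut,N,SNE,high,Y,MAT,medium
CT,Quinnipiac,N,SNE,high,N,MAT,high
CT,Housatonic,N,SNE,high,N,MAT,high
NY,Hudson,Y,SNE,high,Y,MAT,high
NJ,Raritan,N,MAT,medium,N,MAT,high
NJ/DE/PA,Delaware,N,MAT,medium,N,MAT,high
MD,Nanticoke,Y,MAT,medium,Y,MAT,high
MD,Susquehanna,N,MAT,medium,N,MAT,high
MD/VA,Potomac,N,MAT,medium,N,MAT,high
VA,Rappahannock,Y,MAT,low,N,MAT,high
VA,York,Y,MAT,low,N,MAT,high
VA,James,Y,MAT,medium,N,MAT,high
NC,Chowan,Y,MAT,high,Y,MAT,high
NC,Roanoke,N,MAT,high,N,MAT,high
NC,Alligator,N,MAT,high,N,MAT,high
NC,Tar-Pamlico,-,-,-,N,MAT,high
NC,Neuse,-,-,-,N,MAT,high
NC,Cape Fear,-,-,-,N,SAT,medium
SC,Pee Dee,-,-,-,N,SAT,medium
SC,Santee,-,-,-,Y,SAT,medium
SC,Cooper,-,-,-,Y,SAT,medium
SC,Edisto,-,-,-,N,SAT,medium
SC/GA,Savannah,-,-,-,N,SAT,medium
GA,Altamaha,-,-,-,N,SAT,medium
FL,St Johns,-,-,-,Y,SAT,high
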