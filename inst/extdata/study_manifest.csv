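"sample_id","epi_uM","da_uM","ht5_uM","medium","n_spectra","split_role"
"A",2,0,0,"urine",22,"repeat"
"B",0,2,0,"urine",21,"repeat"
"C",0,0,2,"urine",22,"repeat"
"D",3,0,7,"urine",26,"held_out_test"
"E",0,8,3,"urine",28,"held_out_test"
"F",7,3,0,"urine",21,"held_out_validation"
"G",3,2,7,"urine",26,"repeat"
"H",1,1,9,"urine",22,"repeat"
"I",2,8,3,"urine",22,"repeat"
"J",6,9,1,"urine",23,"repeat"
"K",7,3,2,"urine",23,"repeat"
"L",9,6,4,"urine",21,"repeat"
"U",0,0,0,"urine",41,"repeat"
"A",2,0,0,"water",25,"repeat"
"B",0,2,0,"water",17,"repeat"
"C",0,0,2,"water",22,"repeat"
"G",3,2,7,"water",41,"repeat"
"H",1,1,9,"water",38,"repeat"
"I",2,8,3,"water",37,"repeat"
"J",6,9,1,"water",93,"repeat"
"K",7,3,2,"water",11,"repeat"
"L",9,6,4,"water",11,"repeat"
"M",3,3,3,"water",11,"repeat"
"U",0,0,0,"water",58,"repeat"
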