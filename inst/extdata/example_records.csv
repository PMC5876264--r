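"athlete_id","age","mri_positive","n_muscles","primary_muscle","location","insertion_involved","transverse_pct","retraction_cm","sagittal_extent_cm","rts_days"
"ex1",21,TRUE,1,"semimembranosus","proximal",FALSE,30.4,0,10,31
"ex2",26,TRUE,1,"biceps_femoris_long_head","middle",FALSE,3.9,0,10.4,7
"ex3",27,TRUE,1,"biceps_femoris_long_head","proximal",FALSE,28.3,0,5.9,13
"ex4",26,TRUE,1,"biceps_femoris_long_head","proximal",FALSE,10.8,0,18,28
"ex5",25,TRUE,1,"biceps_femoris_long_head","distal",FALSE,8.1,0,12,40
"ex6",25,TRUE,1,"semimembranosus","proximal",FALSE,9.3,0,9,24
"ex7",26,TRUE,1,"biceps_femoris_long_head","middle",FALSE,0.9,0,4.6,12
"ex8",30,TRUE,2,"biceps_femoris_short_head","distal",FALSE,16.1,0,13.1,24
"ex9",27,TRUE,1,"biceps_femoris_long_head","middle",FALSE,5.8,0,11.7,19
"ex10",20,FALSE,0,,,FALSE,0,0,0,14
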