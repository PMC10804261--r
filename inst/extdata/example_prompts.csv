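"subject_id","day_index","weekday","slot_index","answered","happy","sad","tired","relaxed","nervous","calm","full_of_energy"
"res_001",1,3,1,TRUE,98,4,4,100,4,99,98
"res_001",1,3,2,TRUE,80,23,25,78,24,78,78
"res_001",1,3,3,TRUE,87,17,18,88,15,86,89
"res_001",1,3,4,FALSE,,,,,,,
"res_001",1,3,5,TRUE,94,7,5,95,7,97,95
"res_001",1,3,6,TRUE,88,16,15,89,18,86,88
"res_001",1,3,7,TRUE,67,18,18,67,16,68,70
"res_001",1,3,8,TRUE,69,21,21,72,21,69,69
"res_001",2,4,1,TRUE,100,7,7,100,8,100,100
"res_001",2,4,2,FALSE,,,,,,,
"res_001",2,4,3,TRUE,74,25,24,75,23,76,74
"res_001",2,4,4,TRUE,89,4,4,90,4,90,89
"res_001",2,4,5,TRUE,99,0,2,99,1,98,100
"res_001",2,4,6,TRUE,100,11,12,98,12,100,100
"res_001",2,4,7,TRUE,88,14,13,87,16,85,88
"res_001",2,4,8,TRUE,86,11,14,89,13,89,88
"res_001",3,5,1,TRUE,77,17,20,76,18,75,76
"res_001",3,5,2,FALSE,,,,,,,
"res_001",3,5,3,TRUE,86,18,17,83,17,86,84
"res_001",3,5,4,TRUE,93,7,5,92,5,92,92
"res_001",3,5,5,FALSE,,,,,,,
"res_001",3,5,6,TRUE,97,10,11,98,12,99,97
"res_001",3,5,7,FALSE,,,,,,,
"res_001",3,5,8,FALSE,,,,,,,
"res_001",4,6,1,TRUE,76,18,15,75,18,75,75
"res_001",4,6,2,FALSE,,,,,,,
"res_001",4,6,3,TRUE,84,24,26,84,24,85,83
"res_001",4,6,4,TRUE,71,15,14,72,15,72,72
"res_001",4,6,5,FALSE,,,,,,,
"res_001",4,6,6,TRUE,92,2,0,92,0,93,90
"res_001",4,6,7,TRUE,86,1,3,89,0,89,86
"res_001",4,6,8,TRUE,97,7,6,98,6,97,98
"res_001",5,7,1,TRUE,85,17,18,83,20,83,84
"res_001",5,7,2,TRUE,78,25,26,80,28,77,80
"res_001",5,7,3,TRUE,92,17,17,92,14,93,93
"res_001",5,7,4,TRUE,85,9,7,83,6,85,85
"res_001",5,7,5,TRUE,100,17,14,100,15,100,100
"res_001",5,7,6,FALSE,,,,,,,
"res_001",5,7,7,TRUE,94,9,9,97,6,94,97
"res_001",5,7,8,TRUE,93,7,5,92,4,93,91
"res_001",6,1,1,TRUE,83,13,15,82,12,82,82
"res_001",6,1,2,TRUE,100,4,2,98,1,100,100
"res_001",6,1,3,TRUE,94,6,7,94,8,94,94
"res_001",6,1,4,TRUE,89,8,10,90,8,91,89
"res_001",6,1,5,FALSE,,,,,,,
"res_001",6,1,6,TRUE,96,1,1,95,4,95,95
"res_001",6,1,7,TRUE,92,6,6,90,4,90,92
"res_001",6,1,8,TRUE,67,16,14,67,15,66,65
"res_001",7,2,1,TRUE,93,4,4,91,4,93,93
"res_001",7,2,2,TRUE,86,7,7,86,10,87,87
"res_001",7,2,3,FALSE,,,,,,,
"res_001",7,2,4,TRUE,96,0,1,96,0,93,96
"res_001",7,2,5,TRUE,100,2,2,100,4,98,98
"res_001",7,2,6,TRUE,83,4,1,86,3,86,84
"res_001",7,2,7,TRUE,98,2,0,98,0,100,99
"res_001",7,2,8,TRUE,91,10,8,94,11,93,94
"con_001",1,6,1,FALSE,,,,,,,
"con_001",1,6,2,FALSE,,,,,,,
"con_001",1,6,3,TRUE,81,21,21,81,20,81,84
"con_001",1,6,4,FALSE,,,,,,,
"con_001",1,6,5,FALSE,,,,,,,
"con_001",1,6,6,FALSE,,,,,,,
"con_001",1,6,7,FALSE,,,,,,,
"con_001",1,6,8,TRUE,91,24,26,92,26,94,93
"con_001",2,7,1,TRUE,64,27,28,66,25,67,66
"con_001",2,7,2,TRUE,87,19,19,89,19,87,86
"con_001",2,7,3,FALSE,,,,,,,
"con_001",2,7,4,FALSE,,,,,,,
"con_001",2,7,5,TRUE,81,25,24,82,25,79,80
"con_001",2,7,6,TRUE,86,15,14,88,14,89,86
"con_001",2,7,7,TRUE,79,19,17,79,18,79,78
"con_001",2,7,8,TRUE,64,33,31,66,30,64,64
"con_001",3,1,1,TRUE,60,32,33,61,33,63,60
"con_001",3,1,2,TRUE,82,11,9,84,12,84,82
"con_001",3,1,3,FALSE,,,,,,,
"con_001",3,1,4,TRUE,76,16,13,73,16,76,76
"con_001",3,1,5,TRUE,76,22,23,78,22,78,78
"con_001",3,1,6,TRUE,73,17,17,75,18,75,73
"con_001",3,1,7,TRUE,79,20,20,76,20,77,76
"con_001",3,1,8,FALSE,,,,,,,
"con_001",4,2,1,TRUE,61,26,27,63,27,63,63
"con_001",4,2,2,TRUE,79,23,20,79,20,79,78
"con_001",4,2,3,TRUE,87,15,15,87,15,89,89
"con_001",4,2,4,TRUE,97,7,7,94,5,94,96
"con_001",4,2,5,TRUE,78,23,25,81,23,81,80
"con_001",4,2,6,TRUE,77,28,27,79,28,77,79
"con_001",4,2,7,TRUE,86,8,10,88,9,87,89
"con_001",4,2,8,TRUE,80,13,12,80,11,81,81
"con_001",5,3,1,TRUE,77,24,24,77,24,76,77
"con_001",5,3,2,TRUE,63,18,18,64,18,66,63
"con_001",5,3,3,TRUE,69,20,19,70,20,69,70
"con_001",5,3,4,TRUE,83,20,21,82,22,81,82
"con_001",5,3,5,TRUE,68,22,20,68,20,65,66
"con_001",5,3,6,TRUE,90,0,2,87,2,89,89
"con_001",5,3,7,TRUE,66,27,27,68,30,66,67
"con_001",5,3,8,FALSE,,,,,,,
"con_001",6,4,1,TRUE,78,8,7,79,7,81,79
"con_001",6,4,2,TRUE,79,0,0,81,0,79,79
"con_001",6,4,3,FALSE,,,,,,,
"con_001",6,4,4,TRUE,85,16,16,86,18,86,86
"con_001",6,4,5,TRUE,77,23,20,78,23,77,77
"con_001",6,4,6,TRUE,76,25,23,77,26,78,79
"con_001",6,4,7,FALSE,,,,,,,
"con_001",6,4,8,TRUE,75,14,14,77,14,74,74
"con_001",7,5,1,TRUE,91,14,15,91,14,91,93
"con_001",7,5,2,TRUE,62,36,35,61,35,61,61
"con_001",7,5,3,TRUE,88,1,4,88,1,88,90
"con_001",7,5,4,TRUE,76,13,14,77,16,79,77
"con_001",7,5,5,TRUE,84,12,12,81,15,83,81
"con_001",7,5,6,TRUE,86,5,5,88,6,89,86
"con_001",7,5,7,TRUE,85,16,17,87,16,88,85
"con_001",7,5,8,TRUE,72,18,18,75,15,72,74
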