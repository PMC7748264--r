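"hemisphere","delta_t","n_nsc","s_t1","s_t2","nsc_s_t1","nsc_s_t2","rediv","nsc_rediv","dls","nsc_dls"
"H01",9,2361,64,63,50,45,0,0,34,24
"H02",9,2248,51,68,42,43,1,1,29,25
"H03",9,1588,39,39,26,33,0,0,17,11
"H04",9,1499,47,43,33,31,0,0,23,17
"H05",9,2406,56,71,45,52,0,0,25,22
"H06",9,2795,68,81,49,57,1,1,33,24
"H07",18,2226,58,67,41,45,3,2,2,1
"H08",18,2735,82,76,59,61,8,8,2,1
"H09",18,1540,32,32,27,22,0,0,0,0
"H10",18,2055,55,62,39,43,3,2,2,2
"H11",18,2290,67,52,43,41,1,1,3,2
"H12",18,2539,64,73,44,54,3,3,0,0
"H13",24,2832,79,68,54,46,6,6,0,0
"H14",24,3018,84,68,56,49,6,4,0,0
"H15",24,2839,87,67,65,41,8,6,0,0
"H16",24,3334,91,74,69,60,7,6,0,0
"H17",24,2181,59,59,41,42,4,4,0,0
"H18",24,2905,93,77,67,56,10,6,0,0
"H19",32,2994,83,77,63,57,7,5,0,0
"H20",32,2314,68,70,45,45,4,1,0,0
"H21",32,2245,58,79,45,56,7,6,0,0
"H22",32,2846,87,84,63,58,7,4,0,0
"H23",32,2867,72,80,56,60,5,4,0,0
"H24",32,2449,65,62,40,43,9,4,0,0
"H25",48,2647,65,64,49,52,7,7,0,0
"H26",48,2075,47,55,35,39,5,4,0,0
"H27",48,2099,59,57,44,41,6,5,0,0
"H28",48,1963,55,54,42,35,7,4,0,0
"H29",48,2127,58,62,43,45,5,4,0,0
"H30",48,3397,76,78,63,53,11,10,0,0
"H31",72,1648,42,50,36,35,4,4,0,0
"H32",72,2028,57,50,37,39,7,6,0,0
"H33",72,2732,88,83,61,62,11,8,0,0
"H34",72,2412,59,65,40,44,8,2,0,0
"H35",72,3177,84,85,56,51,9,5,0,0
"H36",72,2396,70,66,51,49,5,1,0,0
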