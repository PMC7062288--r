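"rho_R","sigma_theta","p0","D_p","r_d","r_s","r_c","p_a","K_p","K_m","beta_p","beta_m","tau_mean","sigma_tau","v_mean","sigma_v","error"
3.16996,19.9491,213.265,0.000254134,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.122315,41.0804,0.521932,98.0512,28.3552,2.4601
3.16996,18.2644,213.265,0.000254134,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.122315,41.0804,3.77447,98.0512,28.3552,2.537
3.50893,19.9491,213.265,0.000254134,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.122315,55.8022,0.521932,98.0512,28.3552,4.07
3.16996,10.9982,193.368,0.000245937,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.47041,50.5251,8.66468,99.4477,96.1938,4.1684
2.85073,13.9376,230.099,7.50423e-05,0.399591,391.384,0.398009,47.3346,5,170.293,0.654349,0.122315,96.2931,8.66468,99.4477,28.3552,4.4351
3.16996,4.17553,193.368,0.000245937,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.47041,53.714,8.66468,99.4477,96.1938,4.4884
0.595831,8.80631,532.622,0.000823208,0.157219,159.545,0.383802,24.0177,57.4332,192.082,0.448596,0.368426,51.0317,52.9357,94.8773,75.5942,4.7094
3.08561,29.9102,600,0.000101031,0.116678,373.31,0.375183,30.6395,267.784,174.179,0.684328,0.360107,81.7951,51.6191,0.362255,96.1938,4.8464
2.05502,13.0283,276.781,0.000254134,0.0486761,391.384,0.619951,47.3346,20.3035,179.808,0.631086,0.209079,77.0961,0,100,28.3552,6.3986
2.7509,8.98647,530.311,7.60145e-05,0.349326,378.807,0.259804,9.84492,223.016,99.7999,0.57319,0.67795,71.53,54.4132,48.5688,59.535,6.4797
3.16996,4.17553,193.368,0.000245937,0.5,347.255,0.498646,26.1221,20.3035,179.808,0.612414,0.47041,53.5118,8.66468,99.4477,96.1938,6.549
3.7754,16.435,213.265,7.50423e-05,0.088569,315.939,0.239254,31.2297,20.3035,179.808,0.654349,0.92607,96.2931,8.66468,99.4477,28.3552,6.7047
3.16996,13.2834,148.788,0.000245937,0.471578,299.614,0.672447,31.2297,20.3035,93.968,0.427541,0.47041,50.5251,8.66468,37.1192,67.0076,6.7275
2.49327,13.2675,179.214,0.000485328,0.325132,395.81,0.860678,26.8054,66.5961,83.4562,0.295579,0.715346,94.0166,79.2914,18.9366,33.091,7.1178
3.16996,19.9491,213.265,0.000254134,0.5,391.384,0.672447,31.2297,5,179.808,0.654349,0.122315,41.0804,0.521932,98.0512,25.3218,7.3691
3.7754,13.0283,276.781,7.50423e-05,0.088569,315.939,0.910675,47.3346,20.3035,192.161,0.512901,0.122315,96.2931,8.66468,99.4477,28.3552,7.5271
3.16996,3.76024,213.265,0.000254134,0.5,365.404,0.956057,31.2297,20.3035,238.598,0.34129,0.1,47.0275,0.521932,100,15.5551,7.5475
3.80685,25.5941,213.265,0.000297338,0.5,400,0.956057,40.2282,64.6038,215.893,0.542006,0.57967,27.2382,64.1135,98.0512,59.535,7.5809
2.04536,32.2613,318.426,0.000790175,0.456045,249.079,0.925687,40.2431,103.571,235.645,0.713027,0.387816,76.2798,58.0787,36.044,33.1842,7.9189
3.16996,4.17553,190.103,0.000245937,0.110491,391.384,0.672447,27.2588,20.3035,244.011,0.329083,0.415715,81.7951,8.66468,99.4477,7.63818,8.2654
3.25204,19.9491,191.973,0.000245937,0.134726,399.617,0.656237,49.1128,5,248.235,0.654349,0.183271,69.366,8.66468,98.0512,32.4032,8.4645
3.16996,30.6918,379.732,0.000245937,0.5,391.384,0.672447,24.8421,43.0522,280.792,0.654349,0.559179,53.714,70.2218,99.4477,94.5188,8.4782
1.34963,14.1708,243.923,0.00015372,0.0218266,254.752,0.779006,37.0167,58.354,170.185,0.753485,0.777055,33.8512,13.2968,47.6937,11.323,8.7037
1.34642,40.6171,473.749,0.000520806,0.048388,373.31,0.25435,36.777,74.4497,149.381,0.923137,0.951943,81.7951,44.1067,72.3387,78.691,8.8103
3.60374,19.9491,213.265,0.000254134,0.5,391.384,0.672447,31.2297,20.3035,179.808,0.654349,0.1,41.0804,0.521932,98.0512,41.3009,8.8429
4.72414,19.9491,218.358,0.000197622,0.134726,376.721,0.656237,49.1128,5,248.235,0.654349,0.183271,69.366,8.66468,98.0512,32.4032,9.0821
3.80685,25.1381,213.265,0.000312575,0.5,400,0.956057,50,51.1934,215.893,0.631086,0.122315,27.2382,0.521932,98.0512,15.5551,9.2072
1.71424,24.0671,287.84,0.000465324,0.44722,76.7717,0.466545,48.6139,115.567,204.058,0.869107,0.261313,94.4768,72.031,79.1079,2.72875,9.2428
1.49521,24.0671,219.066,0.000762874,0.13394,168.211,0.466545,12.9185,115.567,113.011,0.869107,0.576611,80.9693,41.4357,52.3612,2.72875,9.2634
3.25204,19.9491,191.973,0.000254134,0.43918,40.1855,0.77188,49.1128,53.6219,179.808,0.707974,0.598072,97.6909,66.4475,98.0512,28.3552,9.2964
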