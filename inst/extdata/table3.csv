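worker_id,concentration_ppm,weight_kg,hours_per_day,days_per_year,tenure_years,rfc,breathing_rate,intake,rq,verified
1,0.6768,63,7,312,25,0.0003128,0.627442,0.107155,146.787,TRUE
2,1.4933,63,7,312,15,0.000313,0.627442,0.141856,194.235,TRUE
3,1.4933,55.5,9,312,25,0.000313,0.599451,0.329663,451.388,TRUE
4,0.6768,54,7,312,1.5,0.000313,0.593401,0.007093,9.71323,TRUE
5,1.4933,49,8,312,2,0.000313,0.571944,0.025334,34.6883,TRUE
6,1.4933,80,7,312,2,0.000313,0.680198,0.016147,22.1095,TRUE
7,0.1678,48,7,312,10,0.000313,0.56739,0.012612,17.2699,TRUE
8,0.1678,63,7,312,11,0.000313,0.627442,0.011689,16.0057,TRUE
9,0.1678,66,9,312,8,0.000313,0.637715,0.010604,14.5200,TRUE
10,0.6768,43,8,312,5,0.000313,0.543098,0.031060,42.5295,TRUE
11,0.6768,54,8,312,3,0.000313,0.593401,0.016214,22.2016,TRUE
12,0.6768,62,9,312,4,0.000313,0.623909,0.022272,30.4966,TRUE
13,1.4933,74,11,312,12,0.000313,0.662981,0.160424,219.659,TRUE
14,1.4933,65,7,312,10,0.000313,0.634344,0.092669,126.886,TRUE
15,1.4933,72,7,312,20,0.000313,0.65693,0.173277,237.258,TRUE
16,1.4933,50,7,312,0.08,0.000313,0.576405,0.000908,1.24405,FALSE
17,1.4933,55,8,312,12,0.000313,0.597453,0.141462,193.695,TRUE
18,1.3891,70,7,312,0.5,0.000307925,0.650709366,0.00410555,1.3891,FALSE
19,1.5328,70,7,312,2,0.000307925,0.650709366,0.01812105,1.5328,FALSE
20,1.3891,45,7,312,1,0.000307925,0.553137966,0.01085759,14.6705,FALSE
21,14.6705,70,7,312,0.83,0.000307925,0.650709366,0.07197656,1.3891,FALSE
22,1.3891,55,7,312,18,0.000307925,0.597452745,0.17271336,1.3891,FALSE
23,1.3891,50,7,312,0.83,0.000307925,0.57640508,0.00845178,1.3891,FALSE
24,1.3891,85,9,312,10,0.000307925,0.693585486,0.09266977,1.3891,FALSE
25,1.3891,52,7,312,3,0.000307925,0.585066321,0.02981505,1.3891,FALSE
26,1.3891,50,7,312,5,0.000307925,0.57640508,0.05091437,0.9282,FALSE
27,1.3891,47,7,312,15,0.000307925,0.562740929,0.15864065,0.0414,FALSE
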