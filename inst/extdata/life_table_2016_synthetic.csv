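# SYNTHETIC life table: monotone-spline interpolation through period-life-table-like
# anchor points, fixed so that e(female, 25) = 57.0 (the worked-example anchor).
# Not an official US 2016 life table; shape is representative only.
sex,age,life_expectancy_years
female,15,66.9
female,16,65.9
female,17,64.89
female,18,63.9
female,19,62.9
female,20,61.91
female,21,60.92
female,22,59.94
female,23,58.96
female,24,57.98
female,25,57
female,26,56.03
female,27,55.06
female,28,54.09
female,29,53.12
female,30,52.16
female,31,51.2
female,32,50.24
female,33,49.28
female,34,48.32
female,35,47.37
female,36,46.41
female,37,45.46
female,38,44.5
female,39,43.55
female,40,42.6
female,41,41.65
female,42,40.7
female,43,39.75
female,44,38.8
female,45,37.85
female,46,36.91
female,47,35.97
female,48,35.03
female,49,34.09
female,50,33.16
female,51,32.24
female,52,31.32
female,53,30.41
female,54,29.5
female,55,28.6
female,56,27.71
female,57,26.82
female,58,25.94
female,59,25.08
female,60,24.22
female,61,23.37
female,62,22.52
female,63,21.69
female,64,20.87
female,65,20.07
female,66,19.27
female,67,18.48
female,68,17.71
female,69,16.95
female,70,16.2
female,71,15.47
female,72,14.75
female,73,14.04
female,74,13.35
female,75,12.67
female,76,12.02
female,77,11.37
female,78,10.75
female,79,10.14
female,80,9.55
female,81,8.98
female,82,8.43
female,83,7.9
female,84,7.39
female,85,6.9
female,86,6.43
female,87,5.98
female,88,5.56
female,89,5.16
female,90,4.78
female,91,4.43
female,92,4.1
female,93,3.79
female,94,3.51
female,95,3.26
female,96,3.03
female,97,2.83
female,98,2.66
female,99,2.52
female,100,2.4
male,15,62.2
male,16,61.27
male,17,60.34
male,18,59.41
male,19,58.47
male,20,57.53
male,21,56.58
male,22,55.64
male,23,54.69
male,24,53.75
male,25,52.8
male,26,51.85
male,27,50.9
male,28,49.95
male,29,49.01
male,30,48.06
male,31,47.11
male,32,46.17
male,33,45.23
male,34,44.28
male,35,43.35
male,36,42.41
male,37,41.48
male,38,40.55
male,39,39.62
male,40,38.7
male,41,37.78
male,42,36.87
male,43,35.96
male,44,35.06
male,45,34.16
male,46,33.27
male,47,32.39
male,48,31.51
male,49,30.64
male,50,29.78
male,51,28.93
male,52,28.08
male,53,27.24
male,54,26.42
male,55,25.6
male,56,24.79
male,57,24
male,58,23.21
male,59,22.43
male,60,21.66
male,61,20.91
male,62,20.16
male,63,19.42
male,64,18.69
male,65,17.97
male,66,17.26
male,67,16.55
male,68,15.86
male,69,15.18
male,70,14.5
male,71,13.83
male,72,13.18
male,73,12.53
male,74,11.89
male,75,11.27
male,76,10.66
male,77,10.06
male,78,9.48
male,79,8.92
male,80,8.37
male,81,7.84
male,82,7.32
male,83,6.83
male,84,6.35
male,85,5.9
male,86,5.47
male,87,5.06
male,88,4.67
male,89,4.31
male,90,3.97
male,91,3.66
male,92,3.38
male,93,3.12
male,94,2.88
male,95,2.68
male,96,2.5
male,97,2.36
male,98,2.24
male,99,2.15
male,100,2.1
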