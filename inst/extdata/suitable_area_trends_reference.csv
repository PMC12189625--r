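species,scenario,period,area_1e3km2,trend_pct
S_horneri,Present,,14.40,
S_macrocarpum,Present,,6.61,
S_patens,Present,,5.61,
S_piluliferum,Present,,13.85,
Total,Present,,16.92,
S_horneri,SSP1-1.9,2030s,10.33,-28.25
S_macrocarpum,SSP1-1.9,2030s,4.34,-34.42
S_patens,SSP1-1.9,2030s,6.17,9.91
S_piluliferum,SSP1-1.9,2030s,10.74,-22.49
Total,SSP1-1.9,2030s,14.12,-16.5
S_horneri,SSP1-1.9,2060s,9.81,-31.87
S_macrocarpum,SSP1-1.9,2060s,3.69,-44.12
S_patens,SSP1-1.9,2060s,5.93,5.78
S_piluliferum,SSP1-1.9,2060s,12.04,-13.09
Total,SSP1-1.9,2060s,15.08,-10.8
S_horneri,SSP1-1.9,2090s,10.21,-29.12
S_macrocarpum,SSP1-1.9,2090s,4.44,-32.89
S_patens,SSP1-1.9,2090s,6.26,11.66
S_piluliferum,SSP1-1.9,2090s,9.73,-29.80
Total,SSP1-1.9,2090s,13.69,-19.0
S_horneri,SSP2-4.5,2030s,12.40,-13.91
S_macrocarpum,SSP2-4.5,2030s,5.46,-17.49
S_patens,SSP2-4.5,2030s,6.29,12.14
S_piluliferum,SSP2-4.5,2030s,13.04,-5.78
Total,SSP2-4.5,2030s,15.83,-6.4
S_horneri,SSP2-4.5,2060s,6.80,-52.81
S_macrocarpum,SSP2-4.5,2060s,2.14,-67.61
S_patens,SSP2-4.5,2060s,4.61,-17.87
S_piluliferum,SSP2-4.5,2060s,12.15,-12.27
Total,SSP2-4.5,2060s,14.71,-13.0
S_horneri,SSP2-4.5,2090s,2.77,-80.78
S_macrocarpum,SSP2-4.5,2090s,1.45,-78.00
S_patens,SSP2-4.5,2090s,4.69,-16.32
S_piluliferum,SSP2-4.5,2090s,11.37,-17.94
Total,SSP2-4.5,2090s,14.11,-16.5
S_horneri,SSP5-8.5,2030s,9.62,-33.18
S_macrocarpum,SSP5-8.5,2030s,3.62,-45.20
S_patens,SSP5-8.5,2030s,5.25,-6.51
S_piluliferum,SSP5-8.5,2030s,14.12,1.93
Total,SSP5-8.5,2030s,15.62,-7.6
S_horneri,SSP5-8.5,2060s,2.37,-83.57
S_macrocarpum,SSP5-8.5,2060s,1.48,-77.63
S_patens,SSP5-8.5,2060s,4.28,-23.70
S_piluliferum,SSP5-8.5,2060s,16.98,22.58
Total,SSP5-8.5,2060s,18.06,6.7
S_horneri,SSP5-8.5,2090s,1.52,-89.42
S_macrocarpum,SSP5-8.5,2090s,0.10,-98.45
S_patens,SSP5-8.5,2090s,0.90,-83.96
S_piluliferum,SSP5-8.5,2090s,18.19,31.29
Total,SSP5-8.5,2090s,19.07,12.5
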