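table,section,row,y2020,y2035,y2050,printed_change_pct
caries,population,16-24,6.879,6.984,6.349,-7.7
caries,population,25-59,30.945,30.177,29.480,-4.7
caries,population,60+,16.884,21.093,22.526,33.4
caries,population,Total,54.709,58.255,58.356,6.7
caries,caries,16-24,0.335,0.244,0.232,-30.7
caries,caries,25-59,10.327,8.241,5.649,-45.3
caries,caries,60+,5.079,7.863,9.623,89.4
caries,caries,Total,15.742,16.349,15.504,-1.5
caries,untreated_caries,16-24,0.191,0.193,0.182,-4.4
caries,untreated_caries,25-59,2.687,3.359,3.559,32.4
caries,untreated_caries,60+,1.399,2.758,3.755,168.3
caries,untreated_caries,Total,4.278,6.311,7.497,75.2
caries,treated_caries,16-24,0.143,0.0517,0.0492,-65.7
caries,treated_caries,25-59,7.639,4.881,2.089,-72.6
caries,treated_caries,60+,3.680,5.104,5.868,59.4
caries,treated_caries,Total,11.464,10.038,8.006,-30.2
periodontal,pocketing,16-24,0.674,0.664,0.629,-6.7
periodontal,pocketing,25-59,14.147,12.955,12.082,-14.6
periodontal,pocketing,60+,10.929,14.068,15.269,39.7
periodontal,pocketing,Total,25.751,27.689,27.980,8.7
periodontal,pocketing_severity,Mild pocketing,20.676,22.234,22.495,8.8
periodontal,pocketing_severity,Moderate pocketing,3.162,2.867,2.489,-21.3
periodontal,pocketing_severity,Severe pocketing,1.912,2.587,2.996,56.7
periodontal,loa_severity,Mild LOA,13.505,15.037,15.666,16.0
periodontal,loa_severity,Moderate LOA,4.352,4.398,4.278,-1.7
periodontal,loa_severity,Severe LOA,0.809,0.916,0.954,18.0
periodontal,loa_severity,Total,18.667,20.353,20.898,12.0
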