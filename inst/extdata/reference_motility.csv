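id,vcl,vsl,vap,lin,str,wob,grade,ratios_consistent
1,13.63,6.02,8.63,44.17,69.76,63.32,C,TRUE
3,27.42,14.65,22.57,53.13,64.91,82.31,B,FALSE
5,19.44,10.51,13.92,54.06,75.50,71.60,C,TRUE
15,11.95,6.27,8.17,52.47,68.37,76.74,C,FALSE
25,15.35,4.99,7.14,32.51,69.89,46.51,C,TRUE
27,10.19,3.63,5.94,35.62,58.29,61.11,C,FALSE
43,5.86,4.62,5.35,78.83,94.37,86.36,D,FALSE
56,20.65,12.46,17.79,60.34,70.04,86.15,C,TRUE
63,13.11,8.05,9.93,61.40,81.07,75.74,C,TRUE
89,25.39,10.66,16.28,39.39,65.48,64.12,B,FALSE
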