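subject,time_days,frac_labeled,T_days
v1,1.4,0.013265612129539,7
v1,2.8,0.0283611339483457,7
v1,4.2,0.0368587410360163,7
v1,5.6,0.0528040992755492,7
v1,7,0.0653849061884395,7
v1,10,0.0652726494065754,7
v1,14,0.0559635021311853,7
v1,21,0.0441981719203137,7
v1,35,0.036763944487535,7
v1,63,0.0211301904148644,7
v1,119,0.012239377350278,7
v2,3,0.0436086899850651,15
v2,6,0.088167373278182,15
v2,9,0.101410552878638,15
v2,12,0.179580115652984,15
v2,15,0.202124745460187,15
v2,18,0.184504613722339,15
v2,22,0.160672774343372,15
v2,29,0.126465425599363,15
v2,43,0.0953210981788138,15
v2,71,0.0655143442817681,15
v2,127,0.0310696537500035,15
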