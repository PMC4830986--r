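substrate,k_obs_1e5,k_obs_se_1e5,gamma_1e8,gamma_se_1e8,d_py_pct,y_1np_pct,dnp,theta0_1e2
Chinese desert dust (CDD),86,4,14,1,96,53,+,2.8
Arizona test dust (ATD),36,1,6.1,0.2,88,58,+,7.7
Kaolin,110,10,18,1,98,60,+,1.5
Montmorillonite A,53,5,9.0,0.8,95,89,+,2.0
Montmorillonite B,29,4,4.9,0.7,84,79,+,5.8
Saponite,39,3,6.6,0.4,82,73,-,0.27
Potassium feldspar,1.1,0.2,0.19,0.03,14,10,-,11
Sodium feldspar,0.30,0.06,0.05,0.01,12,6,-,58
Feldspar,0.86,0.14,0.15,0.02,17,4,-,27
Limestone,1.4,0.1,0.24,0.01,18,5,-,21
Dolomite,0.83,0.15,0.14,0.03,16,4,-,11
Calcium sulfate,1.5,0.5,0.25,0.09,6,0,-,49
Quartz,1.7,0.1,0.28,0.01,9,5,-,63
Aluminum oxide,0.25,0.00,0.04,0.00,2,1,-,6.7
Iron (III) oxide,9.0,3.3,1.5,0.6,17,0,-,6.9
Titanium (IV) oxide,1.4,0.0,0.24,0.00,14,3,-,5.2
Montmorillonite K10,250,20,43,3,100,6,+,0.72
ATD with NH3 titration,15,2,2.5,0.4,62,31,-,7.7
Graphite,1.9,0.1,0.32,0.01,9,1,-,2.6
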