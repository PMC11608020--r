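date,tmax,tmin,tmean,rhmax,rhmin,rhmean,rs,u2
2012-04-01,18.9223542041668,9.40974942171602,14.1660518129414,73.7786795314158,39.6389877658658,56.7088336486408,19.8728614828077,2.61998496248974
2012-04-02,23.2422812424506,13.0661329840098,18.1542071132302,68.0662475552639,29.527468369196,48.79685796223,15.6437782263081,2.43044995672109
2012-04-03,16.4318752305385,2.73178828675058,9.58183175864452,86.8447927474886,60.7406255318465,73.7927091396676,19.2791614926006,2.62883263710111
2012-04-04,8.03398584836248,-2.11538816143902,2.95929884346173,69.859106845335,43.3936021886949,56.626354517015,20.4842984184357,3.49363670231406
2012-04-05,22.1133524901883,8.32619006130593,15.2197712757471,76.3842142710816,56.3487268236584,66.36647054737,21.8895860493326,3.8819724333607
2012-04-06,15.8222840656727,5.70430354129641,10.7632938034845,63.2818285614425,23.7824458968878,43.5321372291651,15.4999056350927,2.80119993032649
2012-04-07,14.3735426302371,1.29563844203394,7.8345905361355,71.074049374994,44.8550840543573,57.9645667146756,14.8972453281306,3.45930824290355
2012-04-08,17.3863831718829,5.75033196809362,11.5683575699883,64.5450332564984,36.4348121551195,50.4899227058089,16.2580198917701,2.48333310297317
2012-04-09,17.6384014049898,3.85486621505959,10.7466338100247,71.7851567296275,48.6049307370562,60.1950437333419,21.2867628856793,2.87438076997616
2012-04-10,20.4585973836503,5.80018097318052,13.1293891784154,62.0048451021331,28.2950543055951,45.1499497038641,16.1668492473586,3.53736344819594
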