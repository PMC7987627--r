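# Univariable robust-regression estimates of the penalty difference
# (prone - supine) reported for the original 116-patient dual-planning
# cohort (raw data not distributed). printed_cutoff is the published
# "range prone better" bound; consistent flags whether that bound is
# reproduced by -intercept/coefficient from the printed (rounded)
# estimates -- where FALSE, the published value was evidently computed
# from unrounded estimates. NA cutoffs were published as not identifiable
# or as a category label.
characteristic,intercept,coefficient,sd,unit,printed_cutoff,printed_direction,significant,consistent
Breast depth ratio prone/supine,1.244,-0.7950,0.2493,ratio,1.6,greater_better,TRUE,TRUE
Breast depth difference prone-supine,0.338,-0.0111,0.0033,mm,31,greater_better,TRUE,FALSE
Breast depth prone,0.444,-0.0057,0.0020,mm,77,greater_better,TRUE,FALSE
Breast volume/body weight ratio,0.278,-0.0564,0.0273,mL/kg,4.9,greater_better,TRUE,TRUE
Lower inner quadrant vs not,-0.176,2.7829,0.5075,binary,NA,less_better,TRUE,NA
Left breast volume supine,0.207,-0.0007,0.0003,mL,282,greater_better,TRUE,FALSE
Right breast volume supine,0.177,-0.0005,0.0002,mL,347,greater_better,TRUE,FALSE
Breast depth supine,0.278,-0.0073,0.0038,mm,38,greater_better,FALSE,TRUE
Weight,0.474,-0.0087,0.0046,kg,54,greater_better,FALSE,TRUE
Body mass index,0.156,-0.0115,0.0143,kg/m2,14,greater_better,FALSE,TRUE
Heart volume supine,0.217,-0.0008,0.0008,mL,263,greater_better,FALSE,FALSE
Height,3.029,-0.0193,0.0118,cm,157,greater_better,FALSE,TRUE
Right lung volume supine,-0.708,0.2071,0.1484,L,3.4,less_better,FALSE,TRUE
Total lung volume supine,-0.640,0.0970,0.0766,L,6.6,less_better,FALSE,TRUE
Left lung volume supine,-0.537,0.1641,0.1542,L,3.3,less_better,FALSE,TRUE
Age,0.261,-0.0074,0.0064,years,35,greater_better,FALSE,TRUE
LAD-chest wall distance,-0.005,-0.0056,0.0102,mm,NA,NA,FALSE,NA
Couch type Varian vs Bionix,-0.124,-0.2865,0.1868,binary,NA,NA,FALSE,NA
Preference prone vs else,-0.130,-0.0437,0.1785,binary,NA,NA,FALSE,NA
Prone penalty score,-2.134,0.8961,0.0389,%dose,2.4,less_better,TRUE,TRUE
Supine penalty score,1.464,-0.7004,0.1008,%dose,2.1,greater_better,TRUE,TRUE
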