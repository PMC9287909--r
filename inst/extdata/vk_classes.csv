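class,oc_min,oc_max,hc_min,hc_max,oc_max_open,hc_max_open,precedence
lipids,0,0.3,1.5,2.5,TRUE,FALSE,1
proteins/amino sugars,0.3,0.67,1.5,2.3,TRUE,FALSE,2
carbohydrates,0.67,1.2,1.5,2.5,FALSE,FALSE,3
unsaturated hydrocarbons,0,0.1,0.7,1.5,TRUE,TRUE,4
lignins,0.1,0.67,0.7,1.5,TRUE,TRUE,5
tannins,0.67,1.2,0.5,1.5,FALSE,TRUE,6
condensed aromatics,0,0.67,0.2,0.7,TRUE,TRUE,7
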