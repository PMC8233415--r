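fish_id,total_length_cm,capture_site,tagging_date,tracking_period,days_detected,total_detections,excluded
419,33,PPA,08/06/2016,504,364,39904,FALSE
424,37,PPA,08/06/2016,379,316,19030,FALSE
429,39,PPA,08/06/2016,367,229,12350,FALSE
3039,56,PPA,11/07/2016,482,279,39932,FALSE
3031,36,PPA,16/06/2017,506,497,57262,FALSE
3038,34,PPA,16/06/2017,506,492,43683,FALSE
3037,35,PPA,20/07/2017,365,339,66705,FALSE
455,37,PPA,21/07/2017,506,504,63186,FALSE
456,38,PPA,21/07/2017,21,21,2150,TRUE
462,45,PPA,22/08/2017,100,59,2623,TRUE
3032,35,TPA,04/10/2016,373,371,105739,FALSE
3033,35,TPA,04/10/2016,506,488,169896,FALSE
3034,33,TPA,04/10/2016,360,355,36868,FALSE
3035,32,TPA,04/10/2016,11,11,2415,TRUE
3036,46,TPA,21/06/2017,506,505,43946,FALSE
459,36,TPA,21/06/2017,506,460,45532,FALSE
457,42,TPA,03/08/2017,506,506,51455,FALSE
458,47,TPA,03/08/2017,506,506,164591,FALSE
460,43,TPA,03/08/2017,506,505,66404,FALSE
461,55,TPA,03/08/2017,506,506,70416,FALSE
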