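site,lon,lat,age_bp,sd,quality
synthetic_site_001,143.0255,-24.1139,30492,121,A
synthetic_site_002,142.4532,-21.4137,31414,716,A
synthetic_site_003,126.6648,-38.1837,36482,111,A
synthetic_site_004,122.5852,-14.602,46092,457,A
synthetic_site_005,142.6621,-18.2228,32978,551,A
synthetic_site_006,140.3346,-21.8417,30147,588,A
synthetic_site_007,123.1761,-40.612,30304,561,A
synthetic_site_008,152.8701,-38.8714,30092,280,A
synthetic_site_009,123.5594,-15.3361,39044,798,A
synthetic_site_010,153.2981,-37.5699,30759,585,A
synthetic_site_011,122.7564,-36.7561,36970,135,A
synthetic_site_012,126.735,-38.5809,36226,171,A
synthetic_site_013,124.3394,-39.5338,36215,436,A
synthetic_site_014,127.9471,-36.5631,36366,429,A
synthetic_site_015,141.4866,-22.0039,30155,286,A
synthetic_site_016,152.9878,-34.9607,30851,162,A
synthetic_site_017,125.886,-11.9829,35471,528,A
synthetic_site_018,123.8823,-38.8053,34734,376,A
synthetic_site_019,123.6311,-12.9797,44755,478,A
synthetic_site_020,152.7859,-39.0255,30157,703,A
synthetic_site_021,126.8408,-36.3578,33649,627,A
synthetic_site_022,142.4654,-23.1604,31883,631,A
synthetic_site_023,144.561,-19.5549,34096,747,A
synthetic_site_024,140.0997,-20.127,33438,330,A
synthetic_site_025,126.4766,-40.9869,35608,209,A
synthetic_site_026,137.7297,-18.9404,31677,251,A
synthetic_site_027,125.2441,-39.1479,35847,179,A
synthetic_site_028,124.8962,-15.0596,42166,237,A
synthetic_site_029,153.4351,-40.5169,30239,700,A
synthetic_site_030,140.6262,-18.1532,30451,259,A
synthetic_site_031,125.5743,-38.6309,35090,637,A
synthetic_site_032,123.6742,-15.0946,32412,532,A
synthetic_site_033,124.4349,-16.4325,33069,498,A
synthetic_site_034,125.7046,-36.5765,30845,208,A
synthetic_site_035,124.1154,-13.4586,30201,124,A
synthetic_site_036,152.6172,-39.106,30492,799,A
synthetic_site_037,125.6695,-35.3433,32122,685,A
synthetic_site_038,126.3027,-35.7312,31095,511,A
synthetic_site_039,124.1197,-38.3114,30452,337,A
synthetic_site_040,140.4162,-20.3752,35949,217,A
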