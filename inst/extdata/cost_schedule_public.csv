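sector,visit,state,strategy,cost_base,cost_low,cost_high
public,0,stable,NSPT_only,760.15,608.12,912.18
public,0,remission,NSPT_only,760.15,608.12,912.18
public,0,unstable,NSPT_only,2551.82,2041.46,3062.18
public,0,stable,NSPT_AMOX_MET,768.55,614.84,922.26
public,0,remission,NSPT_AMOX_MET,768.55,614.84,922.26
public,0,unstable,NSPT_AMOX_MET,2560.22,2048.18,3072.26
public,0,stable,NSPT_AZ,767.05,613.64,920.46
public,0,remission,NSPT_AZ,767.05,613.64,920.46
public,0,unstable,NSPT_AZ,2558.72,2046.98,3070.46
public,1,stable,,572.12,457.70,686.54
public,1,remission,,1698.82,1359.06,2038.58
public,1,unstable,,2373.78,1899.02,2848.54
public,2,stable,,572.12,457.70,686.54
public,2,remission,,1698.82,1359.06,2038.58
public,2,unstable,,2373.78,1899.02,2848.54
public,3,stable,,572.12,457.70,686.54
public,3,remission,,1698.82,1359.06,2038.58
public,3,unstable,,2373.78,1899.02,2848.54
public,4,stable,,625.46,500.37,750.55
public,4,remission,,1698.82,1359.06,2038.58
public,4,unstable,,3152.12,2521.70,3782.54
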