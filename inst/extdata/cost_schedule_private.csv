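sector,visit,state,strategy,cost_base,cost_low,cost_high
private,0,stable,NSPT_only,650.00,500.00,900.00
private,0,remission,NSPT_only,650.00,500.00,900.00
private,0,unstable,NSPT_only,4987.50,2000.00,8075.00
private,0,stable,NSPT_AMOX_MET,690.00,530.00,950.00
private,0,remission,NSPT_AMOX_MET,690.00,530.00,950.00
private,0,unstable,NSPT_AMOX_MET,5027.50,2030.00,8105.00
private,0,stable,NSPT_AZ,690.00,530.00,950.00
private,0,remission,NSPT_AZ,690.00,530.00,950.00
private,0,unstable,NSPT_AZ,5027.50,2030.00,8105.00
private,1,stable,,338.75,127.50,550.00
private,1,remission,,2977.50,1155.00,4800.00
private,1,unstable,,4947.50,1795.00,8100.00
private,2,stable,,338.75,127.50,550.00
private,2,remission,,2977.50,1155.00,4800.00
private,2,unstable,,4947.50,1795.00,8100.00
private,3,stable,,338.75,127.50,550.00
private,3,remission,,2977.50,1155.00,4800.00
private,3,unstable,,4947.50,1795.00,8100.00
private,4,stable,,488.75,227.50,750.00
private,4,remission,,2977.50,1155.00,4800.00
private,4,unstable,,5885.00,2170.00,9600.00
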