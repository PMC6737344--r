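measure,group,time,m,sd
guilt,ACTIVE,pre,0.14,0.55
guilt,CONTROL,pre,0.15,0.64
guilt,ACTIVE,post,0.12,0.43
guilt,CONTROL,post,0.18,0.46
indignation,ACTIVE,pre,0.40,0.60
indignation,CONTROL,pre,0.06,0.53
indignation,ACTIVE,post,0.13,0.42
indignation,CONTROL,post,0.28,0.36
guilt_vs_indignation,ACTIVE,pre,-0.26,0.38
guilt_vs_indignation,CONTROL,pre,0.09,0.40
guilt_vs_indignation,ACTIVE,post,-0.01,0.28
guilt_vs_indignation,CONTROL,post,-0.10,0.38
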