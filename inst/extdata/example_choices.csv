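subject_id,group,task,trial_index,item_a,item_b,choice,rt
demo01,CON,preference,1,2,6,6,1.608
demo01,CON,preference,2,5,6,6,1.765
demo01,CON,preference,3,1,6,6,1.538
demo01,CON,preference,4,1,2,2,1.743
demo01,CON,preference,5,3,5,5,1.314
demo01,CON,preference,6,1,3,3,1.557
demo01,CON,preference,7,1,5,5,1.103
demo01,CON,preference,8,2,4,4,1.771
demo01,CON,preference,9,3,6,6,1.313
demo01,CON,preference,10,4,6,6,0.948
demo01,CON,preference,11,2,5,5,1.149
demo01,CON,preference,12,2,3,3,2.06
demo01,CON,preference,13,1,4,4,1.94
demo01,CON,preference,14,3,4,3,0.62
demo01,CON,preference,15,4,5,4,0.515
demo02,MTL,preference,1,4,5,5,1.492
demo02,MTL,preference,2,5,6,5,1.3
demo02,MTL,preference,3,3,6,6,0.81
demo02,MTL,preference,4,2,3,3,1.776
demo02,MTL,preference,5,2,5,5,1.64
demo02,MTL,preference,6,3,5,5,2.192
demo02,MTL,preference,7,2,4,2,1.941
demo02,MTL,preference,8,1,5,5,1.461
demo02,MTL,preference,9,2,6,6,1.322
demo02,MTL,preference,10,1,2,1,1.613
demo02,MTL,preference,11,1,6,6,1.81
demo02,MTL,preference,12,1,4,4,1.895
demo02,MTL,preference,13,1,3,3,1.232
demo02,MTL,preference,14,3,4,3,0.924
demo02,MTL,preference,15,4,6,6,2.435
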