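specimen_id,region,joint_type,n_fused,n_total
ctl_E9_01,cervical,vertebral_body,0,12
ctl_E9_01,thoracic,vertebral_body,0,10
ctl_E9_01,lumbar,vertebral_body,0,9
ctl_E9_01,cervical,spinous_process,0,11
ctl_E9_01,thoracic,spinous_process,0,9
ctl_E9_01,lumbar,spinous_process,0,8
im4_E9_01,cervical,vertebral_body,3,10
im4_E9_01,thoracic,vertebral_body,4,9
im4_E9_01,lumbar,vertebral_body,7,10
im4_E9_01,cervical,spinous_process,9,9
im4_E9_01,thoracic,spinous_process,6,8
im4_E9_01,lumbar,spinous_process,7,7
im4_E9_02,cervical,vertebral_body,5,11
im4_E9_02,thoracic,vertebral_body,3,10
im4_E9_02,lumbar,vertebral_body,4,8
im4_E9_02,cervical,spinous_process,10,10
im4_E9_02,thoracic,spinous_process,5,7
im4_E9_02,lumbar,spinous_process,6,6
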