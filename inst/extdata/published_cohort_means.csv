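keypoint,level,region,control,pd,inph,p_inph_vs_pd,starred
ear_r,upper,trunk,-2.15,-2.07,-1.99,0.101,FALSE
head,upper,trunk,-2.15,-1.99,-1.89,0.036,TRUE
ear_l,upper,trunk,-2.15,-1.98,-1.89,0.044,TRUE
eye_r,upper,trunk,-2.15,-1.98,-1.90,0.094,FALSE
eye_l,upper,trunk,-2.15,-1.98,-1.90,0.089,FALSE
shoulder_r,upper,trunk,-2.15,-1.98,-1.90,0.044,TRUE
neck,upper,trunk,-2.16,-2.00,-1.91,0.059,FALSE
shoulder_l,upper,trunk,-2.16,-2.00,-1.90,0.024,TRUE
nose,upper,trunk,-2.16,-1.99,-1.91,0.118,FALSE
elbow_r,upper,limb,-2.25,-2.07,-1.99,0.196,FALSE
elbow_l,upper,limb,-2.26,-2.06,-1.97,0.102,FALSE
middle_finger_r,upper,limb,-2.31,-2.15,-2.02,0.035,TRUE
wrist_r,upper,limb,-2.31,-2.14,-2.02,0.049,TRUE
thumb_r,upper,limb,-2.33,-2.16,-2.04,0.045,TRUE
middle_finger_l,upper,limb,-2.33,-2.10,-2.04,0.408,FALSE
thumb_l,upper,limb,-2.35,-2.12,-2.06,0.494,FALSE
wrist_l,upper,limb,-2.35,-2.11,-2.04,0.272,FALSE
knee_l,lower,trunk,-2.20,-2.04,-1.92,0.023,TRUE
hip_r,lower,trunk,-2.20,-2.05,-1.94,0.019,TRUE
hip_l,lower,trunk,-2.21,-2.04,-1.95,0.093,FALSE
knee_r,lower,trunk,-2.21,-2.03,-1.91,0.015,TRUE
buttocks,lower,trunk,-2.21,-2.06,-1.95,0.019,TRUE
toe_l,lower,limb,-2.28,-2.05,-1.92,0.038,TRUE
toe_r,lower,limb,-2.29,-2.06,-1.92,0.012,TRUE
ankle_l,lower,limb,-2.32,-2.09,-1.95,0.018,TRUE
ankle_r,lower,limb,-2.35,-2.10,-1.96,0.015,TRUE
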