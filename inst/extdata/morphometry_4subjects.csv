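subject,sex,age,height_cm,weight_kg,ra_axis_major,ra_axis_minor,ivc_max,ivc_min,svc_max,svc_min,left_brachiocephalic_max,left_brachiocephalic_min,right_brachiocephalic_max,right_brachiocephalic_min,left_common_iliac_max,left_common_iliac_min,right_common_iliac_max,right_common_iliac_min,left_subclavian_max,left_subclavian_min,right_subclavian_max,right_subclavian_min
1,M,64,173,67,3.99,2.03,2.85,0.53,1.84,0.45,1.29,1.19,1.46,0.78,1.98,0.56,1.55,1.05,1.12,0.61,1.50,0.55
2,F,58,170,66,3.24,1.92,3.04,1.38,1.24,0.47,1.39,0.81,1.42,0.43,1.64,1.10,1.94,1.20,1.07,0.37,0.61,0.07
3,F,55,178,76,4.64,1.85,3.30,0.90,2.28,0.73,1.98,1.18,1.39,0.78,2.27,0.96,1.72,0.77,1.29,0.23,1.21,0.47
4,F,56,171,99,5.04,1.73,2.40,0.55,1.61,0.60,2.15,0.63,1.95,1.20,2.29,1.51,2.03,0.98,1.14,0.48,0.82,0.20
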