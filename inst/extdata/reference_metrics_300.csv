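Cls,Count,F1,TP,TN,FP,FN,ACC,IoU,bbIoU,mAUC,Precision,Recall
6,300,0.77,2417.41,94777.63,432.32,676.65,0.99,0.65,0.38,0.39,0.85,0.78
5,300,0.74,2670.96,94389.35,479.80,763.89,0.99,0.62,0.46,0.37,0.85,0.78
4,300,0.72,871.88,97029.50,166.04,236.59,1.00,0.55,0.42,0.35,0.84,0.79
3,300,0.74,977.20,96889.34,215.41,222.06,1.00,0.59,0.39,0.39,0.82,0.81
2,300,0.64,409.78,97535.78,140.10,218.34,1.00,0.33,0.28,0.33,0.75,0.65
1,300,0.65,396.02,97564.11,123.58,220.30,1.00,0.35,0.29,0.32,0.76,0.64
0,300,0.54,125.57,97775.43,68.55,334.45,1.00,0.14,0.19,0.20,0.65,0.27
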