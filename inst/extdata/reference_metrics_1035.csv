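Cls,Count,F1,TP,TN,FP,FN,ACC,IoU,bbIoU,mAUC,Precision,Recall
6,1035,0.75,2814.15,93923.13,697.20,869.52,0.98,0.61,0.49,0.38,0.80,0.76
5,1035,0.72,3140.11,93426.73,831.94,905.22,0.98,0.59,0.56,0.37,0.79,0.78
4,1035,0.68,861.58,96943.25,228.44,270.73,0.99,0.51,0.53,0.33,0.79,0.76
3,1035,0.73,935.46,96909.83,235.43,223.27,1.00,0.56,0.54,0.36,0.80,0.81
2,1035,0.65,586.78,97251.42,245.84,219.95,1.00,0.42,0.41,0.33,0.70,0.73
1,1035,0.65,578.17,97275.17,229.28,221.37,1.00,0.44,0.43,0.32,0.72,0.72
0,1035,0.50,128.96,97857.93,70.05,247.06,1.00,0.15,0.22,0.17,0.65,0.34
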