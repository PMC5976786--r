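activity,behavior,mean_pct,min_pct,max_pct,prop,kappa
cognitive_games,GP,2.19,0.24,5.60,0.83,0.70
cognitive_games,GFE,5.31,1.79,12.24,0.83,0.71
cognitive_games,GG,88.46,81.86,92.19,0.87,0.78
cognitive_games,NoneH,4.04,2.27,6.65,0.76,0.59
cognitive_games,LIP,0.03,0.00,0.23,NA,NA
cognitive_games,NRLTG,58.96,10.58,100.00,0.87,0.76
cognitive_games,NoneT,41.01,0.00,89.43,0.87,0.75
cognitive_games,RoP,0.67,0.00,2.89,NA,NA
cognitive_games,RoFE,0.06,0.00,0.43,NA,NA
cognitive_games,MG,64.13,49.94,75.97,0.77,0.59
cognitive_games,SOApos,0.16,0.00,1.57,NA,NA
cognitive_games,NoneAH,34.98,23.94,47.18,0.82,0.67
robot_play,GP,13.70,3.16,22.41,0.82,0.69
robot_play,GFE,4.48,0.42,12.29,0.75,0.59
robot_play,GG,73.30,59.26,96.16,0.81,0.70
robot_play,NoneH,8.52,0.27,15.69,0.67,0.46
robot_play,LIP,0.42,0.00,3.48,NA,NA
robot_play,NRLTG,41.67,6.80,100.00,0.81,0.71
robot_play,NoneT,57.91,0.00,93.21,0.89,0.79
robot_play,RoP,0.41,0.00,1.31,NA,NA
robot_play,RoFE,0.11,0.00,0.32,NA,NA
robot_play,MG,45.03,6.49,84.33,0.80,0.70
robot_play,SOApos,0.18,0.00,1.72,NA,NA
robot_play,NoneAH,54.27,15.09,92.21,0.88,0.77
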