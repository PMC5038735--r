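family,indicator,scale,F,p
pupil,pupil_diameter,pixels,2544.09,0
blink,blink_count,count,156.92,0
blink,blink_rate,per second,133.89,0
fixation,fixation_count,count,15.64,0
fixation,fixation_rate,per second,560.07,0
fixation,fixation_duration,ms,18.12,0
fixation,fixation_position_x,pixels,14.74,0
fixation,fixation_position_y,pixels,0.15,0.83
saccade,saccade_count,count,50.76,0
saccade,saccade_rate,per second,4.28,0.04
saccade,saccade_duration,ms,127.73,0
saccade,saccade_amplitude,degrees,34.44,0
regression,regression_count,count,742.83,0
regression,regression_rate,per second,905.39,0
regression,regression_length,pixels,1.71,0.19
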