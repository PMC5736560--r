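- cytokine: IL1ra
  condition: nil
  model_id: M2_exponential
  beta1: -0.073819293699121
  omega: 1.392572982317255
  sigma: 0.2
  beta0: 97.0
  value_12y: 40.0
  iiv_cv: 244.0
  quantifiable: yes
- cytokine: IL2
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.26863624117952
  sigma: 0.2
  beta0: 2.0
  value_12y: 2.0
  iiv_cv: 200.0
  quantifiable: no
- cytokine: IL4
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.26863624117952
  sigma: 0.2
  beta0: 2.0
  value_12y: 2.0
  iiv_cv: 200.0
  quantifiable: no
- cytokine: IL6
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.26863624117952
  sigma: 0.2
  beta0: 2.0
  value_12y: 2.0
  iiv_cv: 200.0
  quantifiable: no
- cytokine: IL10
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.26863624117952
  sigma: 0.2
  beta0: 2.0
  value_12y: 2.0
  iiv_cv: 200.0
  quantifiable: no
- cytokine: IFNg
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.402557770359941
  sigma: 0.2
  beta0: 5.4
  value_12y: 5.4
  iiv_cv: 248.0
  quantifiable: yes
- cytokine: IP10
  condition: nil
  model_id: M2_exponential
  beta1: 0.0
  omega: 0.838538618751861
  sigma: 0.2
  beta0: 1071.0
  value_12y: 1071.0
  iiv_cv: 101.0
  quantifiable: yes
- cytokine: TNFa
  condition: nil
  model_id: M2_exponential
  beta1: -0.079625953752286
  omega: 0.653575830481762
  sigma: 0.2
  beta0: 19.5
  value_12y: 7.5
  iiv_cv: 73.0
  quantifiable: yes
- cytokine: IL1ra
  condition: SEB
  model_id: M2_exponential
  beta1: -0.061026656304869
  omega: 0.959915342461868
  sigma: 0.2
  beta0: 1666.0
  value_12y: 801.0
  iiv_cv: 123.0
  quantifiable: yes
- cytokine: IL2
  condition: SEB
  model_id: M2_exponential
  beta1: -0.073871043903312
  omega: 0.403061940274324
  sigma: 0.2
  beta0: 46834.0
  value_12y: 19301.0
  iiv_cv: 42.0
  quantifiable: yes
- cytokine: IL4
  condition: SEB
  model_id: M2_exponential
  beta1: 0.104966805392976
  omega: 0.896070782016036
  sigma: 0.2
  beta0: 458.0
  value_12y: 1614.0
  iiv_cv: 111.0
  quantifiable: yes
- cytokine: IL6
  condition: SEB
  model_id: M2_exponential
  beta1: 0.0
  omega: 0.912543256381306
  sigma: 0.2
  beta0: 2847.0
  value_12y: 2847.0
  iiv_cv: 114.0
  quantifiable: yes
- cytokine: IL10
  condition: SEB
  model_id: M2_exponential
  beta1: 0.055114085199315
  omega: 0.675207157001637
  sigma: 0.2
  beta0: 2190.0
  value_12y: 4243.0
  iiv_cv: 76.0
  quantifiable: yes
- cytokine: IFNg
  condition: SEB
  model_id: M2_exponential
  beta1: 0.057985490108513
  omega: 0.856234096947852
  sigma: 0.2
  beta0: 19200.0
  value_12y: 38503.0
  iiv_cv: 104.0
  quantifiable: yes
- cytokine: IP10
  condition: SEB
  model_id: M2_exponential
  beta1: 0.0
  omega: 0.570321692362348
  sigma: 0.2
  beta0: 190133.0
  value_12y: 190133.0
  iiv_cv: 62.0
  quantifiable: yes
- cytokine: TNFa
  condition: SEB
  model_id: M2_exponential
  beta1: 0.069079757793982
  omega: 0.601317620140401
  sigma: 0.2
  beta0: 4740.0
  value_12y: 10859.0
  iiv_cv: 66.0
  quantifiable: yes
- cytokine: IL1ra
  condition: PHA
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.183975737781757
  sigma: 0.2
  beta0: 505.0
  value_12y: 505.0
  iiv_cv: 175.0
  quantifiable: yes
- cytokine: IL2
  condition: PHA
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.319858462345953
  sigma: 0.2
  beta0: 225.0
  value_12y: 225.0
  iiv_cv: 217.0
  quantifiable: yes
- cytokine: IL4
  condition: PHA
  model_id: M2_exponential
  beta1: 0.135915971832514
  omega: 1.27178061125191
  sigma: 0.2
  beta0: 358.0
  value_12y: 1829.0
  iiv_cv: 201.0
  quantifiable: yes
- cytokine: IL6
  condition: PHA
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.43142667789696
  sigma: 0.2
  beta0: 1263.0
  value_12y: 1263.0
  iiv_cv: 260.0
  quantifiable: yes
- cytokine: IL10
  condition: PHA
  model_id: M2_exponential
  beta1: 0.146212156073968
  omega: 0.994756851503797
  sigma: 0.2
  beta0: 146.0
  value_12y: 844.0
  iiv_cv: 130.0
  quantifiable: yes
- cytokine: IFNg
  condition: PHA
  model_id: M2_exponential
  beta1: 0.098081441665327
  omega: 1.018637824274006
  sigma: 0.2
  beta0: 413.0
  value_12y: 1340.0
  iiv_cv: 135.0
  quantifiable: yes
- cytokine: IP10
  condition: PHA
  model_id: M2_exponential
  beta1: 0.0
  omega: 0.896070782016036
  sigma: 0.2
  beta0: 97973.0
  value_12y: 97973.0
  iiv_cv: 111.0
  quantifiable: yes
- cytokine: TNFa
  condition: PHA
  model_id: M2_exponential
  beta1: 0.080962784212434
  omega: 1.114757270528678
  sigma: 0.2
  beta0: 352.0
  value_12y: 930.0
  iiv_cv: 157.0
  quantifiable: yes
- cytokine: IL1ra
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.568114096613001
  sigma: 0.2
  beta0: 372.0
  value_12y: 372.0
  iiv_cv: 327.0
  quantifiable: yes
- cytokine: IL2
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.149739547491235
  omega: 1.933847212268806
  sigma: 0.2
  beta0: 65.0
  value_12y: 392.0
  iiv_cv: 641.0
  quantifiable: yes
- cytokine: IL4
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.098647508084035
  omega: 1.732214067116076
  sigma: 0.2
  beta0: 15.0
  value_12y: 49.0
  iiv_cv: 437.0
  quantifiable: yes
- cytokine: IL6
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.148040999758106
  omega: 2.302213633992229
  sigma: 0.2
  beta0: 22.0
  value_12y: 130.0
  iiv_cv: 1412.0
  quantifiable: yes
- cytokine: IL10
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.0
  omega: 1.287248338643914
  sigma: 0.2
  beta0: 15.0
  value_12y: 15.0
  iiv_cv: 206.0
  quantifiable: yes
- cytokine: IFNg
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.11064984620319
  omega: 1.004407013825234
  sigma: 0.2
  beta0: 22.0
  value_12y: 83.0
  iiv_cv: 132.0
  quantifiable: yes
- cytokine: IP10
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.058007396034133
  omega: 1.445284459805035
  sigma: 0.2
  beta0: 5601.0
  value_12y: 11235.0
  iiv_cv: 266.0
  quantifiable: yes
- cytokine: TNFa
  condition: C_albicans
  model_id: M2_exponential
  beta1: 0.065412894151089
  omega: 1.1617470938298
  sigma: 0.2
  beta0: 26.0
  value_12y: 57.0
  iiv_cv: 169.0
  quantifiable: yes
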