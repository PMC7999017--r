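group,characteristic,level,count,group_n
COPD,sex,male,8,15
CTRL,sex,male,8,15
COPD,smoking,current,7,15
COPD,smoking,former,8,15
CTRL,smoking,current,5,15
CTRL,smoking,never,10,15
COPD,phenotype,emphysema,7,15
COPD,phenotype,bronchitis,8,15
COPD,frequent_exacerbator,yes,9,15
COPD,frequent_exacerbator,no,6,15
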