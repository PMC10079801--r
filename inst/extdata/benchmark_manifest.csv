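dataset,n,d,n_anomalies,source
annthyroid,7129,21,534,ODDS repository (Stony Brook)
arrhythmia,452,274,66,ODDS repository (Stony Brook)
breastw,683,9,239,UCI ML repository / semantic anomaly benchmarks
cardiotocography,2114,21,176,DAMI benchmark collection (Campos et al.)
diabetes,768,8,268,UCI ML repository (Pima Indians)
heart_disease,270,13,10,DAMI benchmark collection (Campos et al.)
hepatitis,80,19,13,DAMI benchmark collection (Campos et al.)
lympho,148,18,6,ODDS repository (Stony Brook)
mammography,11183,6,260,ODDS repository (Stony Brook)
musk,3062,166,97,ODDS repository (Stony Brook)
pima,768,8,268,UCI ML repository (Pima Indians)
thyroid,3772,6,93,ODDS repository (Stony Brook)
vertebral,240,6,30,ODDS repository (Stony Brook)
wbc,278,30,21,ODDS repository (Stony Brook)
wdbc,367,30,10,DAMI benchmark collection (Campos et al.)
wpbc,198,33,47,DAMI benchmark collection (Campos et al.)
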