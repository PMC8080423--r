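who_class,tbs_class,group,cell_type,count
1,1,normal,superficial squamous epithelial,74
2,1,normal,intermediate squamous epithelial,70
3,1,normal,columnar epithelial,98
4,2,abnormal,mild squamous non-keratinizing dysplasia,182
5,3,abnormal,moderate squamous non-keratinizing dysplasia,146
6,3,abnormal,severe squamous non-keratinizing dysplasia,197
7,4,abnormal,squamous cell carcinoma in situ intermediate,150
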