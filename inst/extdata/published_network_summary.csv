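group,species,n,degree_mean,degree_sd,eigenvector_mean,eigenvector_sd,betweenness_mean,betweenness_sd,clustering_mean,clustering_sd
West,capuchin,18,17.78,1.31,0.49,0.33,18.08,1.31,0.88,0.09
West,squirrel_monkey,9,10.44,2.40,0.02,0.007,29.44,24.50,0.77,0.19
East,capuchin,17,23.41,3.36,0.48,0.31,17.79,9.34,0.79,0.03
East,squirrel_monkey,17,24.94,4.59,0.09,0.04,12.93,13.05,0.79,0.06
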