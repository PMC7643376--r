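cutoff: -0.075
metadata: >-
  Published 33-pair RNA-binding-protein gene-pair prognostic signature for
  lung adenocarcinoma. Coefficients from a lasso Cox fit on the TCGA-LUAD
  HTSeq-FPKM discovery cohort; cutoff -0.075 chosen by 3-year
  time-dependent ROC analysis; externally validated on GSE72094. Pair
  orientation as published: the indicator scores 1 when gene_a expression
  strictly exceeds gene_b within a sample.
n_pairs: 33
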