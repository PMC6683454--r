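cohort,outcome,biomarker,sensitivity,specificity,ppv,npv,consistent
voided,upstaging,PSA,86.7,27.9,23.4,89.1,TRUE
voided,upgrading,PSA,82.6,27.0,29.7,80.6,TRUE
voided,risk_increase,PSA,85.0,27.4,26.9,85.3,TRUE
voided,upstaging,three_gene,52.3,72.5,32.6,85.6,TRUE
voided,upgrading,three_gene,50.7,67.5,36.9,78.6,TRUE
voided,risk_increase,three_gene,45.8,71.3,33.4,80.7,TRUE
voided,upstaging,three_gene_psa,56.8,65.2,29.4,85.6,TRUE
voided,upgrading,three_gene_psa,47.8,74.6,41.2,79.3,TRUE
voided,risk_increase,three_gene_psa,89.8,27.0,27.9,89.4,TRUE
voided,upstaging,two_gene,50.0,73.9,32.8,85.3,TRUE
voided,upgrading,two_gene,50.7,69.3,35.7,78.1,FALSE
voided,risk_increase,two_gene,45.8,71.3,33.4,80.7,TRUE
voided,upstaging,two_gene_psa,54.5,66.7,27.7,84.6,FALSE
voided,upgrading,two_gene_psa,40.3,81.6,45.0,78.5,TRUE
voided,risk_increase,two_gene_psa,89.8,27.0,27.9,89.4,TRUE
catheterized,upstaging,PSA,73.1,51.4,27.7,88.2,TRUE
catheterized,upgrading,PSA,66.1,64.8,41.2,87.3,FALSE
catheterized,risk_increase,PSA,58.2,62.6,32.8,82.7,TRUE
catheterized,upstaging,three_gene,68.7,43.7,23.7,84.6,TRUE
catheterized,upgrading,three_gene,63.8,54.8,34.5,80.2,TRUE
catheterized,risk_increase,three_gene,30.2,82.4,35.0,79.0,TRUE
catheterized,upstaging,three_gene_psa,60.9,63.3,29.7,86.4,TRUE
catheterized,upgrading,three_gene_psa,56.9,79.2,50.5,83.1,TRUE
catheterized,risk_increase,three_gene_psa,56.6,62.1,31.2,81.4,FALSE
catheterized,upstaging,two_gene,67.2,53.9,27.1,86.6,TRUE
catheterized,upgrading,two_gene,84.5,3.6,24.7,38.4,TRUE
catheterized,risk_increase,two_gene,35.8,75.8,31.7,79.0,TRUE
catheterized,upstaging,two_gene_psa,65.6,64.9,27.5,86.5,FALSE
catheterized,upgrading,two_gene_psa,55.2,80.5,51.4,82.8,TRUE
catheterized,risk_increase,two_gene_psa,58.5,61.2,32.2,82.4,TRUE
voided,upstaging,partin,53.3,77.0,37.1,86.6,TRUE
voided,upstaging,three_gene_partin,75.0,60.3,32.5,90.5,TRUE
voided,upstaging,two_gene_partin,43.2,91.3,55.7,86.3,TRUE
catheterized,upstaging,partin,56.5,79.8,41.6,82.4,FALSE
catheterized,upstaging,three_gene_partin,61.0,79.8,43.5,88.9,TRUE
catheterized,upstaging,two_gene_partin,59.3,80.8,44.0,88.6,TRUE
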