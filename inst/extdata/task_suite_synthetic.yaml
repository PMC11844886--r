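# Synthetic benchmark task suite: 20 tasks, 4 per complexity level 1..5.
# Prompts reference the synthetic data files produced by stage_task_data().
- id: c1_read_subjects
  prompt: >-
    I have a tab separated file called "subjects.txt". Read it and tell me
    how many rows and columns it has.
  files: [subjects.txt]
  components: [read_file]
- id: c1_read_expression
  prompt: >-
    I have a tab separated gene expression file called "leukemiaExp.txt"
    with gene names in the first column. Read it and print the first five
    rows.
  files: [leukemiaExp.txt]
  components: [read_file]
- id: c1_read_metadata
  prompt: >-
    Read the tab separated file "metadata.txt" and list its column names.
  files: [metadata.txt]
  components: [read_file]
- id: c1_read_protein
  prompt: >-
    I have a tab separated protein abundance table called "proteinExp.txt".
    Read it and report its dimensions.
  files: [proteinExp.txt]
  components: [read_file]
- id: c2_filter_subjects
  prompt: >-
    Read the tab separated file "subjects.txt" and count how many subjects
    belong to each value of the group column.
  files: [subjects.txt]
  components: [read_file, wrangle]
- id: c2_transpose_expression
  prompt: >-
    Read the tab separated gene expression file "leukemiaExp.txt" (gene
    names in the first column, samples in the remaining columns), transpose
    it so rows are samples, and print the dimensions of the result.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle]
- id: c2_top_variable
  prompt: >-
    Read the tab separated file "leukemiaExp.txt" with gene names in the
    first column. Compute the variance of each gene across samples and
    print the names of the 10 most variable genes.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle]
- id: c2_sort_metadata
  prompt: >-
    Read the tab separated file "metadata.txt", sort the rows by the age
    column in decreasing order, and print the sorted table.
  files: [metadata.txt]
  components: [read_file, wrangle]
- id: c3_variance_hist
  prompt: >-
    Read the tab separated gene expression file "leukemiaExp.txt" (gene
    names in the first column). Compute per-gene variances and save a
    histogram of the log10 variances to a PDF file.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle, visualize]
- id: c3_age_boxplot
  prompt: >-
    Read the tab separated file "subjects.txt", convert the age column to
    numeric, and save a boxplot of age by group to a PDF file.
  files: [subjects.txt]
  components: [read_file, wrangle, visualize]
- id: c3_kmeans_samples
  prompt: >-
    Read the tab separated file "leukemiaExp.txt" with gene names in the
    first column. Scale the expression matrix and cluster the samples into
    2 groups with k-means; print the cluster assignment of each sample.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle, ml_stats]
- id: c3_age_ttest
  prompt: >-
    Read the tab separated file "subjects.txt" and test with a t-test
    whether age differs between the two values of the group column. Print
    the p-value.
  files: [subjects.txt]
  components: [read_file, wrangle, ml_stats]
- id: c4_cluster_heatmap
  prompt: >-
    I have the following gene expression data, "leukemiaExp.txt". The file
    is tab separated. The table has gene names on the first column. Each
    row is a gene and each column is a distinct sample. Filter genes based
    on their variability so we retain the most variable top 20 genes.
    Based on these variable genes cluster the samples, and save a heatmap
    of the filtered matrix with the cluster assignment to a PDF file.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle, visualize, ml_stats]
- id: c4_pca_plot
  prompt: >-
    Read the tab separated file "leukemiaExp.txt" (gene names in the first
    column). Run a principal component analysis on the samples and save a
    scatter plot of the first two principal components to a PDF file.
  files: [leukemiaExp.txt]
  components: [read_file, wrangle, visualize, ml_stats]
- id: c4_hclust_dendrogram
  prompt: >-
    Read the tab separated protein abundance file "proteinExp.txt" (protein
    names in the first column). Keep the 15 most variable proteins, run a
    hierarchical clustering of the samples on them, and save the dendrogram
    to a PDF file.
  files: [proteinExp.txt]
  components: [read_file, wrangle, visualize, ml_stats]
- id: c4_lm_diagnostics
  prompt: >-
    Read the tab separated file "subjects.txt", fit a linear model of age
    on group, print the model summary, and save a residuals-versus-fitted
    plot to a PDF file.
  files: [subjects.txt]
  components: [read_file, wrangle, visualize, ml_stats]
- id: c5_expression_metadata
  prompt: >-
    I have a tab separated gene expression file "leukemiaExp.txt" (gene
    names in the first column) and a tab separated sample annotation file
    "metadata.txt". Keep the 20 most variable genes, cluster the samples
    with k-means into 2 groups, compare the clusters with the status
    column of the annotation, and save a PCA plot of the samples to a PDF
    file.
  files: [leukemiaExp.txt, metadata.txt]
  components: [read_file, wrangle, visualize, ml_stats, multi_dataset]
- id: c5_two_omics
  prompt: >-
    Read the tab separated files "leukemiaExp.txt" and "proteinExp.txt"
    (feature names in the first column of each). Restrict both to their
    shared sample columns, compute the correlation between the mean gene
    expression and mean protein abundance per sample, test it with
    cor.test, and save a scatter plot of the two means to a PDF file.
  files: [leukemiaExp.txt, proteinExp.txt]
  components: [read_file, wrangle, visualize, ml_stats, multi_dataset]
- id: c5_subjects_metadata
  prompt: >-
    Read the tab separated files "subjects.txt" and "metadata.txt". Merge
    them on their subject columns, test with a t-test whether age differs
    by the status column, and save a boxplot of age by status to a PDF
    file.
  files: [subjects.txt, metadata.txt]
  components: [read_file, wrangle, visualize, ml_stats, multi_dataset]
- id: c5_pca_by_group
  prompt: >-
    Read the tab separated gene expression file "leukemiaExp.txt" (gene
    names in the first column) and the tab separated file "subjects.txt".
    Run a PCA on the expression samples, test whether the first principal
    component differs between the groups in subjects.txt, and save the PCA
    scatter plot to a PDF file.
  files: [leukemiaExp.txt, subjects.txt]
  components: [read_file, wrangle, visualize, ml_stats, multi_dataset]
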