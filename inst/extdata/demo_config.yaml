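# Demo pipeline configuration: a small two-region phantom cohort.
cohort:
  shape: [44, 24, 24]
  regions:
    Hippo:
      lower: [3, 3, 3]
      upper: [20, 20, 20]
    Cortex:
      lower: [25, 3, 3]
      upper: [42, 20, 20]
  nSubjects: 6
  jitterSd: 0.5
regrid:
  factor: 4
regions: Hippo
cellTypes: [Glia, Oligodendrocytes]
alpha: 0.05
predictor:
  latentDim: 3
  epochs: 150
  numTrees: [100, 250]
  mtry: [1, 3]
  minNodeSize: [1, 5]
out: pipeline_output
seed: 11
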