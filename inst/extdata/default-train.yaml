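# Committed training defaults. The optimizer settings follow the standard
# fine-tuning recipe for a BERT-family encoder; desk-scale runs with the
# TinyEncoder typically override lr/epochs (see the package vignette).
learningRate: 2.0e-5
warmupProportion: 0.15
batchSize: 8
epochs: 20
maxSeqLen: 128
seed: 42
lossWeights: [1.0, 1.0, 1.0]
# encoder stand-in dimensions
dEmb: 16
d: 32
# decoding
threshold: 0.5
maxSpanLen: 30
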