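# Published per-participant benchmark metrics for the three learning
# strategies on the 15-participant smartwatch stress dataset (columns:
# Acc, P, R, F1; 4-decimal display precision).  Used as arithmetic
# inputs: the pipeline's reporting conventions (F1 from P and R, macro
# averaging, half-up rounding) must reproduce the printed summary cells.

reference_individual <- data.frame(
  acc = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.9994, 0.9970, 1, 1),
  p   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.9980, 0.9960, 1, 1),
  r   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1.0000, 0.9941, 1, 1),
  f1  = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.9990, 0.9951, 1, 1))

reference_centralized <- data.frame(
  acc = c(0.9414, 0.9317, 0.9660, 0.9571, 0.8833, 0.9511, 0.9772, 0.8545,
          0.9244, 0.9957, 0.9475, 0.9353, 0.8837, 0.9437, 0.9404),
  p   = c(0.8250, 0.9809, 0.8916, 0.8716, 0.9658, 0.8726, 0.9827, 0.9674,
          1.0000, 0.9880, 0.8540, 0.8812, 0.8575, 0.8400, 0.9098),
  r   = c(1.0000, 0.7809, 1.0000, 1.0000, 0.5853, 0.9720, 0.9401, 0.4771,
          0.7495, 0.9980, 0.9851, 0.9127, 0.7475, 1.0000, 0.8994),
  f1  = c(0.9041, 0.8696, 0.9427, 0.9314, 0.7288, 0.9196, 0.9609, 0.6390,
          0.8568, 0.9930, 0.9149, 0.8967, 0.7987, 0.9130, 0.9046))

reference_federated <- data.frame(
  acc = c(0.9131, 0.7565, 0.9969, 0.7259, 0.8511, 0.8700, 0.8578, 0.7796,
          0.7820, 0.9390, 0.9524, 0.9097, 0.7620, 0.8880, 0.8778),
  p   = c(0.8675, 0.9872, 1.0000, 1.0000, 1.0000, 1.0000, 1.0000, 1.0000,
          1.0000, 0.9950, 1.0000, 0.9917, 1.0000, 0.9967, 1.0000),
  r   = c(0.8089, 0.1670, 0.9887, 0.0589, 0.4447, 0.5484, 0.5227, 0.1835,
          0.2781, 0.8016, 0.8337, 0.7123, 0.2288, 0.6232, 0.6110),
  f1  = c(0.8372, 0.2857, 0.9943, 0.1113, 0.6156, 0.7083, 0.6866, 0.3101,
          0.4352, 0.8879, 0.9093, 0.8291, 0.3724, 0.7669, 0.7585))
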