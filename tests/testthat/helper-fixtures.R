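# shared fixtures, built once per test run

base_cfg <- builtin_base_case()
base_strategies <- build_strategies(base_cfg)

# scenario whose only costs are drug acquisition (for closed-form checks)
drug_cost_only <- function(cfg = base_cfg) {
  cfg$monitoring <- monitoring_costs(0, 0, 0, 0)
  cfg$bsc <- bsc_costs(0, 0, 0, 0)
  cfg
}

# reference values as printed in the source cost-utility analysis (2020 AUD)
reference_table <- data.frame(
  strategy = c("adalimumab", "etanercept", "guselkumab", "ixekizumab",
               "risankizumab", "secukinumab", "tildrakizumab", "ustekinumab"),
  qaly = c(1.554, 1.538, 1.584, 1.581, 1.587, 1.582, 1.568, 1.558),
  cost = c(42384, 45602, 49720, 48635, 49084, 42696, 39930, 44924),
  icur_vs_tildrakizumab = c(-172379, -192307, 607746, 674829, 479834,
                            194524, NA, -492183))
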