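# Deterministic seed substreams: unit k of a run with master seed s gets
# seed derive_seed(s, k). Tree fits and imputation draws within a cycle are
# seeded independently by their counter, so results do not depend on
# execution order.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483647 * 1103 + 7919 * as.double(counter)) %%
               2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
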