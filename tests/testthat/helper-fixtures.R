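# shared fixtures built in code

# noiseless decay data frame on a standard reactor time grid
noiseless_decay <- function(k, p = 0,
                            times = c(0, 600, 1800, 3600, 7200)) {
  data.frame(time_s = times, py_fraction = p + (1 - p) * exp(-k * times))
}

# standard exposure conditions used across tests
gas_3ppmv <- function() gas_conditions(ppmv = 3)
gas_50ppbv <- function() gas_conditions(ppbv = 50)

# draw a tie-free sample (distinct values guaranteed)
sample_no_ties <- function(n) sort(stats::runif(n)) + seq_len(n) * 1e-6
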