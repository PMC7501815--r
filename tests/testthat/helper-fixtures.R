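# Shared fixtures: the worked-example genotype (16 leaves, phyllochron 40)
# and constant benign forcing. All derived expectations in the tests were
# computed by hand / independent arithmetic from the model equations.

example_genotype <- function(n_final = 16) {
  genotype_parameters(n_final = n_final, a_tip = 40, b_tip = 20,
                      a_ll1 = 60, b_ll1 = 100, a6 = 5, b = -2.3, c = 2.5,
                      w6 = 70, r_rad = 10)
}

benign_env <- function(days = 60, temperature = 28, vpd = 1, psi = -0.05,
                       rad = 1.15) {
  environment_series(day = seq_len(days) - 1L, temperature = temperature,
                     vpd = vpd, psi = psi, rad = rad)
}

# random valid genotype for property-style tests (draw under a set seed)
random_genotype <- function() {
  genotype_parameters(
    n_final = sample(8:30, 1),
    a_tip = stats::runif(1, 25, 60), b_tip = stats::runif(1, -30, 60),
    a_ll1 = stats::runif(1, 40, 90), b_ll1 = stats::runif(1, 20, 200),
    a6 = stats::runif(1, 3, 7), b = stats::runif(1, -3, 0),
    c = stats::runif(1, 0, 4), w6 = stats::runif(1, 50, 100),
    r_rad = stats::runif(1, 0, 20))
}
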