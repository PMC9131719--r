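# Small lattice and candidate set for oracle-equivalence tests
tiny_grid <- function() {
  posterior_grid(gamma_max = c(3, 10, 30), f_max = c(1, 1.5, 2.5),
                 beta_octaves = c(2, 4), trunc_delta = c(0.2, 0.8))
}

tiny_candidates <- function() {
  tibble::tibble(fm = c(1, 1.5, 2), M = c(0.2, 0.5, 0.9))
}

standard_observer <- function(...) {
  observer_spec(iocsf_true = iocsf_params(10, 1.5, 3, 0.5), ...)
}

# psychometric probability recomputed from first principles (independent of
# the package's vectorised implementation)
oracle_prob_correct <- function(M, f, gmax, fmax, beta, delta,
                                lapse = 0.04, slope = 3.5) {
  sp <- log10(gmax) - log10(2) *
    ((log10(f) - log10(fmax)) / (log10(2^beta) / 2))^2
  s <- if (f < fmax && sp < log10(gmax) - delta) log10(gmax) - delta else sp
  0.5 + (0.5 - lapse) * (1 - exp(-(M * 10^s)^slope))
}
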