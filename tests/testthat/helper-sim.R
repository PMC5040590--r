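# Shared fixtures, all generated in code.

# independent oracle for the single-site free-analyte closed form: numeric
# root of the complex-concentration quadratic C^2 - C(S+P+K) + SP = 0
oracle_free_analyte <- function(s, p, k) {
  roots <- Re(polyroot(c(s * p, -(s + p + k), 1)))
  cplx <- roots[roots >= -1e-9 & roots <= min(s, p) + 1e-9]
  s - min(cplx)
}

# noiseless competition experiment + exact calibration model
make_noiseless_competition <- function(kd, analyte_total = 25,
                                       titrant = serial_dilution(10000, 11),
                                       rmax = 120, k_half = 40) {
  free <- free_analyte_competition(analyte_total, titrant, kd)
  list(calibration = structure(list(rmax = rmax, k_half = k_half),
                               class = "hyperbolic_model"),
       experiment = list(
         analyte_total_nM = analyte_total,
         points = data.frame(titrant_nM = titrant,
                             response_RU = hyperbolic_response(rmax, k_half,
                                                               free))))
}

# random small multi-ligand systems for property tests
random_system <- function(n_lig, n_site) {
  list(L = stats::runif(n_lig, 0, 2000),
       T = stats::runif(n_site, 0, 2000),
       K = matrix(10^stats::runif(n_lig * n_site, 0, 4), n_lig, n_site))
}
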