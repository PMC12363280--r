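# shared fixtures: reference geometry, discretizations and a power-law
# curve builder used across the suite

ref_geom <- hydrogel_geometry(radius = 3.25e-3, height = 5e-3)
ref_disc <- discretization(31L, 300)
fine_disc <- discretization(301L, 30)

static_schedule <- release_schedules()$static

# exact power-law release curve M_t/M_inf = a * t^n (fractions), expressed
# in percent on a loading of m_inf micrograms
power_law_curve <- function(a, n, times = c(0.5, 1, 2, 4, 6), m_inf = 100) {
  frac <- a * times^n
  release_curve(times, frac * m_inf, m_inf)
}

# transport parameters with a prescribed Biot number k L / d_eff
params_at_biot <- function(biot, d_eff = 1.04e-9, geom = ref_geom,
                           c_eq = 0) {
  transport_params(d_eff, biot * d_eff / geom$height, c_eq)
}

# textbook perfect-sink slab series (insulated base, zero surface
# concentration): fraction released at dimensionless time tau = D t / L^2
perfect_sink_fraction <- function(tau, n_terms = 2000) {
  m <- seq_len(n_terms)
  lam <- (2 * m - 1) * pi / 2
  vapply(tau, function(tt) 1 - sum(8 / ((2 * m - 1)^2 * pi^2) *
                                     exp(-lam^2 * tt)), numeric(1))
}
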