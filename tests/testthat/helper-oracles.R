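# Independent oracles used across the suite. These deliberately re-derive
# each quantity with single-expression arithmetic or brute-force numerics
# so they never share code with the implementation they check.

# saturation vapour pressure oracle: Antoine form in mmHg, converted to kPa
svp_kpa_oracle <- function(t) exp(18.6686 - 4030.183 / (t + 235)) * 0.133322

# brute-force bisection for the clothing-surface balance
bisect_tcl_oracle <- function(tsk, ta, tr, icl, fcl, hc, fr, hr,
                              tol = 1e-12, maxit = 500) {
  f <- function(tcl) {
    (tsk - tcl) / icl - fcl * hc * (tcl - ta) - fr * hr * (tcl - tr)
  }
  lo <- min(tsk, ta, tr) - 5
  hi <- max(tsk, ta, tr) + 5
  stopifnot(f(lo) * f(hi) <= 0)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# small synthetic city reused by several files
fixture_city <- function(seed = 101) {
  generate_city(city_spec(n_districts = 6, population = 100000,
                          nrow = 64, ncol = 64, cellsize = 100,
                          green_fraction = 0.2, landuse_cellsize = 20,
                          seed = seed))
}

fixture_run_config <- function(dir, seed = 5) {
  cfg <- unclass(default_run_config(seed = seed, output_dir = dir))
  cfg$city <- utils::modifyList(cfg$city, list(
    nrow = 32L, ncol = 32L, cellsize = 200, population = 50000,
    n_districts = 4L, landuse_cellsize = 50))
  read_run_config(cfg)
}
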