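# Shared fixtures.  The default-geometry phantom takes a few seconds to
# build, so it is generated once per test run and reused.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

term_phantom <- function() cached("term", generate_phantom(phantom_config(seed = 11L)))

early_phantom <- function() cached(
  "early", generate_phantom(phantom_config(stage = "early", seed = 11L)))

# small random acquisition volume for oracle tests
random_volume <- function(seed, nr = 4L, nb = 3L, nz = 12L, nx = 7L) {
  set.seed(seed)
  acquisition_volume(array(stats::runif(nr * nb * nz * nx), c(nr, nb, nz, nx)),
                     acquisition_geometry(nr, nb, nx, nz))
}

# random flat-junction boundary set compatible with a geometry
flat_boundaries <- function(geometry, ilm, ipl, opl) {
  m <- function(v) matrix(v, geometry$n_bscans, geometry$n_ascans)
  boundary_set(list(ILM = m(ilm), IPL_INL = m(ipl), OPL_ONL = m(opl)), geometry)
}

# brute-force per-voxel slab classification: returns per-slab projected image
# by explicit looping, independent of project_slab's vectorized mask logic
brute_project <- function(flow_arr, upper, lower, projection, lower_inclusive) {
  nb <- dim(flow_arr)[1]; nz <- dim(flow_arr)[2]; nx <- dim(flow_arr)[3]
  out <- matrix(0, nb, nx)
  for (b in seq_len(nb)) for (x in seq_len(nx)) {
    zu <- floor(upper[b, x] + 0.5)
    zl <- floor(lower[b, x] + 0.5) + if (lower_inclusive) 1L else 0L
    vals <- c()
    for (z0 in 0:(nz - 1)) if (z0 >= zu && z0 < zl)
      vals <- c(vals, flow_arr[b, z0 + 1L, x])
    out[b, x] <- if (length(vals) == 0) 0
                 else switch(projection, max = max(vals), mean = mean(vals),
                             sum = sum(vals))
  }
  out
}
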