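# Shared fixtures, built in code at test time.

# Small deterministic DEM for stencil tests.
rand_dem <- function(nr = 5, nc = 5, seed = 42, cell_size = 10) {
  set.seed(seed)
  new_grid(matrix(rnorm(nr * nc, 50, 5), nr, nc), cell_size = cell_size,
           y_origin = nr * cell_size)
}

# Plane DEM z = ax*x + ay*y evaluated at cell centres.
plane_dem <- function(ax, ay, nr = 7, nc = 7, cell_size = 1) {
  g <- new_grid(matrix(0, nr, nc), cell_size = cell_size,
                y_origin = nr * cell_size)
  ctr <- cell_centers(g)
  g$values <- matrix(ax * ctr[, 1] + ay * ctr[, 2], nr, nc)
  g
}

interior <- function(m) m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]

# Small shared seascape + virtual species for the heavier module tests.
tiny_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_environment(nx = 30, ny = 22, cell_size = 90,
                                     seed = 404)
    cache
  }
})

tiny_species <- function(detection = 0.8, spatial_sd = 0, seed = 9,
                         n_hauls = 140, stack = tiny_env()) {
  vs <- virtual_species(c(depth = -2, dshore = -1), intercept = 1.5,
                        detection_prob = detection, spatial_sd = spatial_sd,
                        spatial_range = 600)
  des <- survey_design(n_hauls = n_hauls)
  generate_species(stack, vs, des, seed = seed, species = "VSP")
}
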