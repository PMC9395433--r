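# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

mesh0 <- function() fixture("mesh0", function() build_icosphere(0))
mesh2 <- function() fixture("mesh2", function() build_icosphere(2))
mesh3 <- function() fixture("mesh3", function() build_icosphere(3))
mesh4 <- function() fixture("mesh4", function() build_icosphere(4))

template3 <- function() fixture("template3", function() make_template(3, seed = 7))
template4 <- function() fixture("template4", function() make_template(4, seed = 7))

paradigm1 <- function() fixture("paradigm1", function() generate_paradigm(1))
design1 <- function() fixture("design1", function() build_design(paradigm1()))

# uniform random unit vectors
random_directions <- function(n, seed = 1) {
  set.seed(seed)
  q <- matrix(stats::rnorm(3 * n), ncol = 3)
  q / sqrt(rowSums(q * q))
}

with_seed_noise <- function(seed, n, sd) {
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

# the scaled-down end-to-end comparison (n = 20 subjects, 2,562-vertex
# meshes, fixed master seed), shared by the acceptance blocks
acceptance_experiment <- function() {
  fixture("acceptance_experiment", function() {
    cfg <- experiment_config(master_seed = 42, n_subjects = 20,
                             mesh_subdivisions = 4,
                             arms = c("surface_unaligned", "surface_cba"))
    run_experiment(cfg, verbose = FALSE)
  })
}
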