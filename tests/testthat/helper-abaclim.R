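# small shared fixtures, built in code

small_domain <- function(nrow = 20, ncol = 25, resolution = 0.01)
  domain_geometry(nrow = nrow, ncol = ncol, lon_origin = 130,
                  lat_origin = -36, resolution = resolution)

# fully valid constant grid
const_grid <- function(value, nrow = 10, ncol = 10, resolution = 0.1,
                       lon = 130, lat = -36, variable = "value")
  raster_grid(matrix(value, nrow, ncol), lon, lat, resolution,
              variable = variable)

# grid with values drawn under a seed, all cells valid
random_grid <- function(seed, nrow = 10, ncol = 10, resolution = 0.1,
                        lon = 130, lat = -36, mean = 0, sd = 1)
  withr::with_seed(seed,
    raster_grid(matrix(rnorm(nrow * ncol, mean, sd), nrow, ncol),
                lon, lat, resolution))

# surveys with a known linear truth on a small noisy baseline
make_surveys <- function(n = 600, species = "A", seed = 1,
                         truth = synthetic_truth(),
                         domain = small_domain(60, 100)) {
  aug <- generate_baseline(domain, "august", truth, noise_sd = 0.3, seed = seed)
  generate_surveys(aug, truth, n, species, seed = seed + 1000)
}
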