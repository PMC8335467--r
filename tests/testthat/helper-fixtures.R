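# Small lattices and canned objects shared across the suite. Everything is
# generated in code; no binary fixtures.

tiny_grid <- function(n = 20, spacing = 2) {
  grid_spec(rep(spacing, 3), rep(-(n - 1) * spacing / 2, 3), rep(n, 3))
}

# centred sphere mask by the voxel-centre-inside rule
sphere_mask <- function(grid, radius, center = c(0, 0, 0)) {
  co <- grid_coords(grid)
  outer(outer((co$x - center[1])^2, (co$y - center[2])^2, "+"),
        (co$z - center[3])^2, "+") <= radius^2
}

# uniform-dose grid over everything
uniform_dose <- function(grid, gy) dose_grid(array(gy, grid$dim), grid)

# a dose grid with given values in a mask, 0 elsewhere
masked_dose <- function(grid, mask, values) {
  arr <- array(0, grid$dim)
  arr[mask] <- values
  dose_grid(arr, grid)
}

identity_registration <- function()
  structure(list(translation = c(0, 0, 0), rotation = c(0, 0, 0)),
            class = "rigid_registration")

# small realized patient shared by several files (cached per session)
.test_patient <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- generate_patient(42)
      grid <- default_grid(tpl)
      planning <- realize_structures(tpl, NULL, grid)
      cache <<- list(tpl = tpl, grid = grid, planning = planning)
    }
    cache
  }
})

noiseless_params <- function(...)
  dose_model_params(noise_amplitude = 0, ...)
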