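# small study configurations reused across tests; subdivision 3 hosts the
# full 34-parcel-per-hemisphere scheme, subdivision 2 a coarser 8-parcel one
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 8, n_parcels_per_hemisphere = 8,
         mesh_subdivision_level = 2, n_timepoints = 90, n_runs = 3,
         rng_seed = 42L),
    list(...)
  )
  do.call(synth_config, args)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 10, mesh_subdivision_level = 3,
         n_timepoints = 120, n_runs = 3, rng_seed = 42L),
    list(...)
  )
  do.call(synth_config, args)
}

# identical-pipelines configuration: no offsets, no noise on the B side,
# no boundary perturbation
identical_config <- function(...) {
  tiny_config(delta_thick_mm = 0, delta_gyr = 0, subject_sd = 0,
              boundary_swap_prob = 0, ...)
}

# single-hemisphere test sphere
test_sphere <- function(level = 2, radius = 20) {
  icosphere(level = level, radius = radius, hemisphere = "left")
}
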