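# Shared fixtures. Everything is generated in code; the phantom spec used
# throughout the suite is desk-scale (coarser ex vivo grid than the
# deployment default) so the whole run stays within CI budgets.

test_spec <- function(...) {
  phantom_spec(spacing_exvivo = 0.12, ...)
}

# small random volume with a given seed
rand_volume <- function(dims = c(16, 16, 16), spacing = rep(0.15, 3),
                        seed = 1) {
  tbmpipe:::with_seed(seed, function()
    tbm_volume(array(rnorm(prod(dims), 100, 15), dims), spacing = spacing))
}

# cached template per modality (building is cheap but not free)
.fixture_env <- new.env()
cached_template <- function(modality = "invivo") {
  key <- paste0("tpl_", modality)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_template(test_spec(), modality)
  .fixture_env[[key]]
}

cached_calibration <- function() {
  if (is.null(.fixture_env$calib))
    .fixture_env$calib <- tbmpipe:::phantom_calibration(test_spec())
  .fixture_env$calib
}

# core mask of a (possibly paired) phantom region in a given geometry:
# label voxels inside the nominal ellipsoid(s)
region_core_mask <- function(spec, geometry, region) {
  grid <- tbmpipe:::world_grid(geometry)
  lab <- tbmpipe:::phantom_labels_at(spec, grid)
  geom <- tbmpipe:::phantom_geometry(spec)
  id <- tbmpipe:::PHANTOM_REGIONS[[region]]
  if (region == "cortex") {
    core <- lab == id
  } else {
    r <- geom$regions[[region]]
    inside <- tbmpipe:::ell_rho2(grid, r$c, r$s) <= 1
    if (isTRUE(r$paired))
      inside <- inside | tbmpipe:::ell_rho2(grid, r$c * c(-1, 1, 1),
                                            r$s) <= 1
    core <- lab == id & inside
  }
  array(core, tbmpipe:::vol_dim(geometry))
}
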