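# Shared expensive objects (meshes, reference solves) built once per test run.
.tcache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.tcache[[name]])) .tcache[[name]] <- force(expr)
  .tcache[[name]]
}

# PFA monopolar reference: fine half-domain mesh + nonlinear field solve at
# 3100 V and baseline temperature
pfa_mono_reference <- function() {
  cached("pfa_mono_ref", {
    cfg <- scenario_config("PFA", "monopolar", mesh_resolution = "fine",
                           half_domain = TRUE)
    mesh <- generate_mesh(build_geometry(cfg))
    fs <- solve_nonlinear_pfa_field(mesh, 37, cfg$applied_voltage)
    f <- lesion_field_vcm_t(mesh, fs$E_elem)
    list(cfg = cfg, mesh = mesh, fs = fs,
         metrics = lesion_metrics(extract_lesion_region(mesh, f, 1000)))
  })
}

# nodal lesion criterion field with NAs (non-tissue nodes) zeroed
lesion_field_vcm_t <- function(mesh, E_elem) {
  f <- ablatr:::lesion_field_vcm(mesh, E_elem)
  f[is.na(f)] <- 0
  f
}

# RFA monopolar reference run (coarse half-domain, full 30 s protocol)
rfa_mono_reference <- function(velocity = 0.06) {
  key <- paste0("rfa_mono_", velocity)
  cached(key, {
    cfg <- scenario_config("RFA", "monopolar", inlet_velocity = velocity,
                           mesh_resolution = "coarse", half_domain = TRUE)
    suppressWarnings(run_rfa(cfg))
  })
}

# small monopolar PFA mesh for quick nonlinear-field tests
pfa_mono_small_mesh <- function() {
  cached("pfa_small_mesh", {
    cfg <- scenario_config("PFA", "monopolar", mesh_resolution = "paper",
                           half_domain = TRUE)
    generate_mesh(build_geometry(cfg))
  })
}
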