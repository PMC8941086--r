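# Shared fixtures, all built in code at test time.

# memoized grids (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# all-true cube grid, centred affine
cube_grid <- function(n = 8, voxel = 2) {
  brain_grid(array(TRUE, dim = rep(n, 3)), centered_affine(rep(n, 3), voxel))
}

# ~16k-voxel ellipsoid at 2 mm: the "reduced grid" for permutation work
small_ellipsoid <- function() memo("small_ellipsoid",
                                   function() ellipsoid_grid(c(30, 34, 30)))

# ~38k-voxel ellipsoid used for the 3-group recovery experiments
recovery_grid <- function() memo("recovery_grid",
                                 function() ellipsoid_grid(c(40, 45, 40)))

# three compact planted-centre sets, pairwise centroid separation >= 30 mm,
# all well inside the recovery grid's mask
recovery_centers <- function() list(
  rbind(c(0, 30, 20), c(10, 34, 10)),
  rbind(c(24, -24, 20), c(30, -16, 10)),
  rbind(c(-24, -24, -14), c(-14, -30, -4)))

recovery_spec <- function(seed, jitter = 5, background = 0.15) {
  synthetic_spec(n_groups = 3, experiments_per_group = c(15, 15, 15),
                 centers_per_group = recovery_centers(),
                 spatial_jitter_sd_mm = jitter,
                 background_foci_rate = background, seed = seed)
}

# small deterministic corpus for I/O tests: foci on voxel centres
toy_corpus <- function() {
  corpus(list(
    experiment_record("s1", "e1", rbind(c(0, 0, 0), c(10, -20, 30)),
                      n_cases = 20, n_controls = 18, diagnosis = "ADHD",
                      task_domain = c("cognitive", "response_inhibition"),
                      valence = "none", medication_naive = TRUE,
                      pct_boys = 80),
    experiment_record("s1", "e2", rbind(c(-8, 12, -6)),
                      n_cases = 15, diagnosis = "DEP",
                      task_domain = "emotion", valence = "negative",
                      medication_naive = NA, pct_boys = NA),
    experiment_record("s2", "e3", rbind(c(20, 22, 24), c(-20, -22, -24)),
                      n_cases = 30, n_controls = 30, diagnosis = "ANX",
                      task_domain = c("emotion", "attention"),
                      valence = "both", medication_naive = FALSE,
                      pct_boys = 55)),
    provenance = "toy")
}

write_toy_tables <- function(corp = toy_corpus(), dir = withr::local_tempdir(),
                             .local_envir = parent.frame()) {
  if (missing(dir)) dir <- withr::local_tempdir(.local_envir = .local_envir)
  foci <- file.path(dir, "foci.csv")
  meta <- file.path(dir, "metadata.csv")
  write_corpus(corp, foci, meta)
  list(foci = foci, meta = meta, dir = dir)
}

# internal spatial helpers used by tests
mask_positions <- magale:::mask_positions
ijk_to_lin <- magale:::ijk_to_lin
in_volume <- magale:::in_volume
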