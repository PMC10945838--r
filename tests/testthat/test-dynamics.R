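tpl <- molecule_template()
ff0 <- force_field(eps_H = 0, eps_E = 0)

test_that("zero temperature, zero force, zero velocity leaves positions unchanged", {
  st <- gen_fibril_bundle(1, spacing = 1.5, template = tpl)  # equilibrium rod
  cfg <- sim_config(n_molecules = 1, box_length = st$box_length,
                    temperature = 0, n_steps = 0, seed = 1)
  out <- step_langevin(st, tpl, ff0, cfg, n_steps = 50)
  expect_equal(out$positions, st$positions, tolerance = 1e-12)
  expect_equal(out$velocities, st$velocities, tolerance = 1e-12)
})

test_that("NVE velocity Verlet conserves energy (relative drift <= 1e-4)", {
  ff <- force_field(0.05, 5)
  cfg <- sim_config(n_molecules = 2, box_length = 15, timestep = 1e-4,
                    n_steps = 10000, seed = 5, snapshot_interval = 200)
  st <- init_system(cfg, tpl)
  out <- colfibril:::run_engine(st, tpl, ff, cfg, cfg$n_steps,
                                cfg$snapshot_interval, seed = 5,
                                thermostat = FALSE)
  E <- out$potential + out$kinetic
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
})

test_that("thermostatted run satisfies equipartition (kinetic energy per dof ~ kT/2)", {
  cfg <- sim_config(n_molecules = 1, box_length = 15, timestep = 0.001,
                    n_steps = 60000, seed = 6, snapshot_interval = 500)
  st <- init_system(cfg, tpl)
  out <- colfibril:::run_engine(st, tpl, ff0, cfg, cfg$n_steps,
                                cfg$snapshot_interval, seed = 6)
  ke <- out$kinetic[-(1:20)] / (3 * tpl$n_beads)   # discard burn-in
  expect_equal(mean(ke), 0.5, tolerance = 0.05)
})

test_that("sampled velocity components have variance kT/m", {
  cfg <- sim_config(n_molecules = 1, box_length = 15, timestep = 0.001,
                    n_steps = 0, seed = 3)
  st <- init_system(cfg, tpl)
  st <- step_langevin(st, tpl, ff0, cfg, n_steps = 2000, seed = 1000)
  samples <- numeric(0)
  for (i in 1:100) {   # snapshots 0.5 tau0 apart: decorrelated velocities
    st <- step_langevin(st, tpl, ff0, cfg, n_steps = 500, seed = 2000 + i)
    samples <- c(samples, as.vector(st$velocities))
  }
  expect_equal(var(samples), 1, tolerance = 0.05)
  expect_equal(mean(samples), 0, tolerance = 0.05)
})

test_that("bond-length variance matches the harmonic prediction kT/(2 k_bond)", {
  cfg <- sim_config(n_molecules = 1, box_length = 15, timestep = 0.001,
                    n_steps = 0, seed = 12)
  st <- init_system(cfg, tpl)
  st <- step_langevin(st, tpl, ff0, cfg, n_steps = 2000, seed = 500)
  bl <- numeric(0)
  for (i in 1:60) {   # 1 tau0 between samples: bond amplitudes decorrelate
    st <- step_langevin(st, tpl, ff0, cfg, n_steps = 1000, seed = 600 + i)
    p <- st$positions
    bl <- c(bl, sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2))[-tpl$n_beads])
  }
  bl <- bl[is.finite(bl)]
  expect_lt(abs(var(bl) - 1 / (2 * 500)) / (1 / (2 * 500)), 0.1)
})

test_that("a wildly unstable timestep raises an instability error", {
  ff <- force_field(0.05, 5)
  cfg <- sim_config(n_molecules = 2, box_length = 15, timestep = 0.5,
                    n_steps = 200, seed = 5)
  st <- init_system(cfg, tpl)
  expect_error(run_simulation(cfg, tpl, ff, state = st), "instability")
})

test_that("trajectories are deterministic given the seed", {
  ff <- force_field(0.05, 5)
  cfg <- sim_config(n_molecules = 4, box_length = 14, n_steps = 400, seed = 9,
                    snapshot_interval = 100)
  a <- run_simulation(cfg, tpl, ff)
  b <- run_simulation(cfg, tpl, ff)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$potential, b$potential)
})

test_that("dynamics are invariant under rigid translation of the initial condition", {
  ff <- force_field(0.05, 5)
  cfg <- sim_config(n_molecules = 3, box_length = 14, n_steps = 300, seed = 2,
                    snapshot_interval = 300)
  st <- init_system(cfg, tpl)
  shift <- c(1.3, -2.1, 0.7)
  st2 <- system_state(sweep(st$positions, 2, shift, `+`), st$velocities,
                      st$box_length, st$n_beads)
  e1 <- total_energy_forces(st, tpl, ff)$energy
  e2 <- total_energy_forces(st2, tpl, ff)$energy
  expect_equal(e1, e2, tolerance = 1e-10)
  a <- colfibril:::run_engine(st, tpl, ff, cfg, 300, 300, seed = 2)
  b <- colfibril:::run_engine(st2, tpl, ff, cfg, 300, 300, seed = 2)
  d1 <- a$final_positions - st$positions
  d2 <- b$final_positions - st2$positions
  # displacements agree up to whole-box wrapping of the output coordinates
  dd <- d1 - d2
  dd <- dd - st$box_length * round(dd / st$box_length)
  expect_lt(max(abs(dd)), 1e-8)
})

test_that("without attractive interactions a dilute system stays unassembled", {
  cfg <- sim_config(n_molecules = 30, box_length = 40, timestep = 0.004,
                    n_steps = 2000, seed = 3, snapshot_interval = 500)
  tr <- run_simulation(cfg, tpl, ff0)
  ac <- assembly_curve(tr)
  expect_lt(max(ac$phi), 0.05)
})

test_that("trajectory text round trip preserves coordinates and metadata", {
  ff <- force_field(0.05, 5)
  cfg <- sim_config(n_molecules = 3, box_length = 14, n_steps = 200, seed = 10,
                    snapshot_interval = 100)
  tr <- run_simulation(cfg, tpl, ff)
  d <- withr::local_tempdir()
  write_trajectory(tr, d)
  back <- read_trajectory(d)
  expect_equal(back$times, tr$times)
  expect_equal(back$snapshots[[2]], tr$snapshots[[2]], tolerance = 1e-9)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$force_field$eps_E, 5)
})
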