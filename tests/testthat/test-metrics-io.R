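test_that("AMI endpoints and the three-sample case", {
  expect_equal(absolute_mixing_index(rep(0.37, 10)), 0)
  expect_equal(absolute_mixing_index(c(rep(1, 20), rep(0, 20))), 1)
  expect_equal(absolute_mixing_index(c(1, 0.5, 0)), 2 / 3)
  expect_equal(absolute_mixing_index(c(1, 0.5, 0), variant = "rms"),
               sqrt(mean(c(0.5, 0, 0.5)^2)) / 0.5)
  expect_error(absolute_mixing_index(c(0, 0, 0)), "mean is zero")
})

test_that("AMI is invariant under reordering and stable under subsampling by 2", {
  set.seed(14)
  n <- 1000
  y <- (seq_len(n) - 0.5) / n
  alpha <- 0.5 + 0.45 * tanh((y - 0.5) * 8)
  a1 <- absolute_mixing_index(alpha)
  expect_identical(absolute_mixing_index(sample(alpha)), a1)
  expect_equal(absolute_mixing_index(alpha[seq(1, n, by = 2)]), a1, tolerance = 1e-3)
})

test_that("extract_profile samples the fluid cells of the nearest station", {
  sc <- unit_scales(1e-6, 1e-6)
  g <- channel_geometry(20e-6, 7e-6, x_m = 15e-6)
  m <- build_channel_mask(g, sc, 2)
  fld <- rep(3.5, prod(m$dims))
  pr <- extract_profile(fld, m, 15e-6)
  expect_equal(nrow(pr), 7L)
  expect_true(all(pr$value == 3.5))
  expect_equal(pr$z, ((1:7) - 0.5) * 1e-6)
  expect_error(extract_profile(fld, m, 40e-6), "outside")
  # sample count matches the printed grids
  m2 <- build_channel_mask(channel_geometry(600e-6, 40e-6, x_m = 500e-6), sc, 2)
  expect_equal(nrow(extract_profile(rep(0, prod(m2$dims)), m2, 500e-6)), 40L)
})

test_that("1D pipeline and field-extraction AMI agree on the analytic field", {
  g <- channel_geometry(600e-6, 40e-6, x_m = 500e-6)
  sc <- unit_scales(1e-6, 1e-6)
  m <- build_channel_mask(g, sc, 2)
  co <- arrayInd(seq_len(prod(m$dims)), m$dims)
  prof1 <- mixing_profile_at_line(g, 0.01, 90e-12)
  # paint the analytic line values into a field and extract them back
  fld <- numeric(prod(m$dims))
  ix <- round(500e-6 / sc$dx + 1.5)
  sel <- co[, 1] == ix & m$role == MF_ROLES[["fluid"]]
  fld[sel] <- prof1$alpha[order(co[sel, 2])]
  pr <- extract_profile(fld, m, 500e-6)
  expect_equal(absolute_mixing_index(pr$value), absolute_mixing_index(prof1),
               tolerance = 1e-12)
})

test_that("droplet tracking recovers synthetic slugs and counts components", {
  sc <- unit_scales(1e-6, 1e-6)
  g <- bifurcation_geometry(l = 50e-6, k = 25e-6, w = 10e-6)
  m <- build_bifurcation_mask(g, sc, 2)
  co <- arrayInd(seq_len(prod(m$dims)), m$dims)
  j <- attr(m, "junction")
  alpha <- numeric(prod(m$dims))
  # rectangular slug from x-cell 11..30 across the full inlet width
  slug <- co[, 1] - 1L >= 11 & co[, 1] - 1L <= 30 & m$role == MF_ROLES[["fluid"]] &
    co[, 2] - 1L >= j$ylo & co[, 2] - 1L <= j$yhi
  alpha[slug] <- 1
  tr <- droplet_track(alpha, m)
  expect_equal(tr$s_um, 10.5, tolerance = 1e-9)   # trailing cell centre
  expect_equal(tr$length_um, 19, tolerance = 1e-9)
  expect_equal(tr$n_components, 1L)
  expect_identical(tr$branch, "inlet")
  # two disjoint blobs
  blob2 <- co[, 1] - 1L >= 40 & co[, 1] - 1L <= 45 & m$role == MF_ROLES[["fluid"]] &
    co[, 2] - 1L >= j$ylo & co[, 2] - 1L <= j$yhi
  alpha[blob2] <- 1
  expect_equal(droplet_track(alpha, m)$n_components, 2L)
  expect_error(droplet_track(numeric(prod(m$dims)), m), "empty")
})

test_that("droplet tracking matches the 1D trajectory rendered to fields", {
  sc <- unit_scales(1e-6, 1e-6)
  g <- bifurcation_geometry(l = 50e-6, k = 25e-6, w = 10e-6, p_top = 0, p_bot = 1e-5)
  m <- build_bifurcation_mask(g, sc, 2)
  net <- bifurcation_network(g, mu = 1e-3, u_in = 0.01, level = "2d")
  traj <- droplet_trajectory(g, net, alpha = 1.2, dl = 10e-6, s0 = 5e-6,
                             t_samples = seq(0, 3e-3, length.out = 7))
  s_path <- mfsim:::bifurcation_path_coordinate(m)
  for (i in seq_len(nrow(traj))) {
    s_te <- traj$s[i]
    cells <- m$role == MF_ROLES[["fluid"]] & s_path >= s_te & s_path <= s_te + 10e-6
    alpha <- as.numeric(cells)
    tr <- droplet_track(alpha, m)
    expect_equal(tr$s_um, min(s_path[cells]) * 1e6)
    expect_lte(abs(tr$s_um - s_te * 1e6), 0.5 + 1e-9)   # within half a cell
  }
})

test_that("profile CSV round-trips and VTK files validate structurally", {
  tmp <- withr::local_tempdir()
  g <- channel_geometry(600e-6, 40e-6, x_m = 500e-6)
  prof <- mixing_profile_at_line(g, 0.01, 90e-12)
  f <- write_profile_csv(prof, file.path(tmp, "p.csv"))
  back <- utils::read.csv(f)
  expect_equal(back$concentration, prof$alpha)
  expect_equal(back$position_um, prof$z * 1e6)

  vtk <- file.path(tmp, "f.vtk")
  write_vtk(vtk, dims = c(6L, 4L), dx = 1e-6,
            scalars = list(rho = runif(24)),
            vectors = list(velocity = matrix(runif(48), 24)))
  expect_true(validate_vtk(vtk))

  rep <- file.path(tmp, "r.json")
  write_report_json(list(ami = 0.5, case = "mix", steps = 10L), rep)
  got <- jsonlite::fromJSON(rep)
  expect_equal(got$ami, 0.5)
  expect_identical(got$case, "mix")
})

test_that("use-case outputs are written with deterministic names", {
  tmp <- withr::local_tempdir()
  cfg <- load_config(example_config("mix_straight"))
  res <- run_use_case("mix", "1d", cfg, out_dir = tmp)
  expect_true(all(file.exists(res$files)))
  expect_true(any(grepl("mix_1d_.*_report\\.json$", res$files)))
  # same config -> same hash -> same file names
  res2 <- run_use_case("mix", "1d", cfg, out_dir = tmp)
  expect_identical(res$files, res2$files)
})
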