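test_that("channel masks reproduce the printed grids and label every cell", {
  sc <- unit_scales(1e-6, 1e-6)
  cases <- list(
    list(l = 500e-6, w = 100e-6, grid = c(500L, 100L)),
    list(l = 600e-6, w = 40e-6, grid = c(600L, 40L)),
    list(l = 3e-6, w = 1e-6, grid = c(3L, 1L)))
  for (cs in cases) {
    g <- channel_geometry(cs$l, cs$w, x_m = cs$l / 2)
    m <- build_channel_mask(g, sc, 2)
    expect_identical(m$dims, cs$grid + 2L)
    tab <- table(factor(m$role, levels = 0:4))
    expect_equal(unname(tab[["0"]]), prod(cs$grid))           # fluid count
    expect_equal(unname(tab[["2"]]), cs$grid[2])              # inlet column
    expect_equal(unname(tab[["3"]]), cs$grid[2])              # outlet column
    expect_equal(sum(tab), prod(m$dims))                      # mask conservation
  }
})

test_that("a minimal 3x1 channel has every fluid cell wall-adjacent", {
  sc <- unit_scales(1e-6, 1e-6)
  m <- build_channel_mask(channel_geometry(3e-6, 1e-6, x_m = 2e-6), sc, 2)
  co <- arrayInd(seq_len(prod(m$dims)), m$dims)
  fl <- which(m$role == MF_ROLES[["fluid"]])
  for (c in fl) {
    nb <- c(c - m$dims[1], c + m$dims[1])
    expect_true(any(m$role[nb] == MF_ROLES[["wall"]]))
  }
})

test_that("3D channel mask has the full left face as inlet", {
  sc <- unit_scales(1e-6, 1e-6)
  g <- channel_geometry(10e-6, 5e-6, h = 4e-6, x_m = 8e-6)
  m <- build_channel_mask(g, sc, 3)
  expect_identical(m$dims, c(12L, 7L, 6L))
  expect_equal(sum(m$role == MF_ROLES[["inlet"]]), 5L * 4L)
  expect_equal(sum(m$role == MF_ROLES[["fluid"]]), 10L * 5L * 4L)
})

test_that("non-representable extents are rejected with the axis named", {
  sc <- unit_scales(1e-6, 1e-6)
  expect_error(build_channel_mask(channel_geometry(10.4e-6, 5e-6, x_m = 8e-6), sc, 2), "'l'")
  expect_error(build_channel_mask(channel_geometry(10e-6, 5.3e-6, x_m = 8e-6), sc, 2), "'w'")
})

test_that("bifurcation mask has one inlet face, two outlet faces, and is connected", {
  sc <- unit_scales(1e-6, 1e-6)
  g <- bifurcation_geometry(l = 500e-6, k = 250e-6, w = 100e-6)
  m <- build_bifurcation_mask(g, sc, 2)
  expect_equal(sum(m$role == MF_ROLES[["inlet"]]), 100L)
  expect_equal(sum(m$role == MF_ROLES[["outlet"]]), 100L)
  expect_equal(sum(m$role == MF_ROLES[["outlet2"]]), 100L)
  expect_equal(sum(m$role == MF_ROLES[["fluid"]]),
               500L * 100L + 100L * 100L + 2L * 250L * 100L)
  expect_true(mask_connected(m))
  # mask conservation
  expect_equal(sum(table(m$role)), prod(m$dims))
})

test_that("degenerate bifurcations are rejected", {
  expect_error(bifurcation_geometry(l = 5e-6, k = 0, w = 2e-6), "'k'")
  expect_error(bifurcation_geometry(l = 5e-6, k = 1e-6, w = 4e-6,
                                    branch_measure = "center"), "exceed")
})

test_that("branch_measure switches the branch extent", {
  sc <- unit_scales(1e-6, 1e-6)
  ge <- bifurcation_geometry(l = 20e-6, k = 10e-6, w = 4e-6)
  gc <- bifurcation_geometry(l = 20e-6, k = 10e-6, w = 4e-6, branch_measure = "center")
  me <- build_bifurcation_mask(ge, sc, 2)
  mc <- build_bifurcation_mask(gc, sc, 2)
  expect_equal(attr(me, "junction")$nb, 10L)
  expect_equal(attr(mc, "junction")$nb, 8L)   # k - w/2
})

test_that("masks connected by flood fill across random channel sizes", {
  sc <- unit_scales(1e-6, 1e-6)
  set.seed(42)
  for (i in 1:5) {
    nx <- sample(4:30, 1); ny <- sample(2:12, 1)
    m <- build_channel_mask(channel_geometry(nx * 1e-6, ny * 1e-6, x_m = nx * 1e-6 / 2), sc, 2)
    expect_true(mask_connected(m))
  }
})
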