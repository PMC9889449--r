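# Fixtures: a large flat square at z = 0 and a second sheet below it.
flat_sheet <- function(z = 0, half = 20) {
  triangle_mesh(rbind(c(-half, -half, z), c(half, -half, z),
                      c(half, half, z), c(-half, half, z)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

test_that("build_hrpr constructs the offset rectangle and resolves orientation", {
  m <- flat_sheet()
  h <- build_hrpr(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), offset_d = 5, spacing = 0.5,
                  mesh = m)
  expect_equal(h$extent_u, 10)
  expect_equal(h$extent_v, 10)
  expect_equal(abs(h$origin[3]), 5)           # plane moved off the surface
  expect_equal(abs(sum(h$u_axis * h$v_axis)), 0, tolerance = 1e-9)
  expect_equal(abs(sum(h$u_axis * h$normal)), 0, tolerance = 1e-9)
  expect_equal(ersr:::hrpr_grid_dims(h), c(21L, 21L))  # floor(extent/spacing)+1 per axis

  # non-perpendicular third corner: second edge is orthogonalized
  h2 <- build_hrpr(c(0, 0, 0), c(10, 0, 0), c(13, 8, 0), offset_d = 2, spacing = 1, mesh = m)
  expect_equal(h2$extent_v, 8)

  expect_error(build_hrpr(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1, 0.5, m), "collinear")
  expect_error(build_hrpr(c(100, 100, 0), c(110, 100, 0), c(110, 110, 0), 5, 1, m),
               "does not face")
})

test_that("generate_grid is uniform, row-major and on the offset plane", {
  m <- flat_sheet()
  h1 <- build_hrpr(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), offset_d = 3, spacing = 1, mesh = m)
  expect_equal(nrow(generate_grid(h1)), 4)    # extent 1x1, spacing 1: corners only

  h <- build_hrpr(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), offset_d = 5, spacing = 0.5,
                  mesh = m)
  g <- generate_grid(h)
  expect_equal(nrow(g), 441)
  expect_equal(min(dist(g)), 0.5, tolerance = 1e-9)  # uniform nearest spacing
  expect_lt(max(abs((sweep(g, 2, h$origin)) %*% h$normal)), 1e-9)  # on the plane
  # row-major, i (u axis) fastest
  expect_equal(g[2, ] - g[1, ], 0.5 * h$u_axis, tolerance = 1e-12)
})

test_that("project_grid maps a flat sheet by pure offset and keeps all hits", {
  m <- flat_sheet()
  h <- build_hrpr(c(-5, -5, 0), c(5, -5, 0), c(5, 5, 0), offset_d = 7, spacing = 1,
                  mesh = m)
  pc <- project_grid(h, m)
  expect_true(all(pc$hit_mask))
  expect_equal(nrow(pc$points), 121)
  expect_equal(pc$points[, 3], rep(0, 121))
  expect_equal(pc$t, rep(7, 121))
  g <- generate_grid(h)
  expect_equal(pc$points[, 1:2], g[, 1:2])  # projection only moves along the normal
})

test_that("with stacked sheets only the superficial surface is selected", {
  two <- triangle_mesh(rbind(flat_sheet(0)$vertices, flat_sheet(-2)$vertices),
                       rbind(flat_sheet(0)$faces, flat_sheet(-2)$faces + 4L))
  h <- build_hrpr(c(-5, -5, 0), c(5, -5, 0), c(5, 5, 0), offset_d = 4, spacing = 1,
                  mesh = two)
  pc <- project_grid(h, two)
  expect_true(all(abs(pc$points[, 3]) < 1e-9))  # never the inner sheet at z = -2
})

test_that("accelerated projection matches the per-triangle oracle exactly", {
  for (s in 1:8) {
    soup <- random_triangle_soup(n_tri = 60 + 40 * s, seed = s)
    h <- build_hrpr(c(1, 1, 20), c(9, 1, 20), c(9, 9, 20), offset_d = 0, spacing = 0.9,
                    mesh = soup)
    pc <- project_grid(h, soup, min_hit_fraction = 0)
    g <- generate_grid(h)
    hits <- 0
    for (i in seq_len(nrow(g))) {
      o <- oracle_raycast(soup$vertices, soup$faces, g[i, ], -h$normal)
      expect_equal(pc$hit_mask[i], !is.null(o))
      if (!is.null(o)) {
        hits <- hits + 1
        expect_equal(pc$points[hits, ], o$point, tolerance = 1e-9)
      }
    }
  }
})

test_that("projection is idempotent on the hit set", {
  soup <- random_triangle_soup(n_tri = 200, seed = 99)
  h <- build_hrpr(c(1, 1, 20), c(9, 1, 20), c(9, 9, 20), offset_d = 0, spacing = 1,
                  mesh = soup)
  pc <- project_grid(h, soup, min_hit_fraction = 0)
  # casting again from the recorded grid nodes reproduces the same hits
  g <- generate_grid(h)
  pc2 <- project_grid(h, soup, min_hit_fraction = 0)
  expect_identical(pc$hit_mask, pc2$hit_mask)
  expect_equal(pc$points, pc2$points)
})

test_that("project_pair keeps only jointly hit nodes with equal cardinality", {
  m <- flat_sheet(half = 30)
  h <- build_hrpr(c(-5, -5, 0), c(5, -5, 0), c(5, 5, 0), offset_d = 6, spacing = 1, mesh = m)
  pp <- project_pair(h, m, m)
  expect_equal(pp$cloud_a, pp$cloud_b)

  # mesh_b shifted so only half the rectangle overlaps both meshes
  mb <- apply_transform(rigid_transform(translation = c(28, 0, 0)), m)
  pp2 <- project_pair(list(h), m, mb, min_points = 1)
  expect_equal(nrow(pp2$cloud_a), nrow(pp2$cloud_b))
  expect_lt(nrow(pp2$cloud_a), 121)
  # disjoint hit sets: error
  mc <- apply_transform(rigid_transform(translation = c(200, 0, 0)), m)
  expect_error(project_pair(list(h), m, mc, min_points = 1), "poorly placed|insufficient")
})

test_that("virtual mesh transforms project identically to moved meshes", {
  soup <- random_triangle_soup(n_tri = 150, seed = 12)
  tr <- random_rigid_transform(20, 5, seed = 5)
  moved <- apply_transform(tr, soup)
  h <- build_hrpr(c(1, 1, 20), c(9, 1, 20), c(9, 9, 20), offset_d = 0, spacing = 1,
                  mesh = soup)
  # rectangle corners move with the mesh: relative geometry is unchanged
  hm <- build_hrpr(apply_transform(tr, c(1, 1, 20)),
                   apply_transform(tr, c(9, 1, 20)),
                   apply_transform(tr, c(9, 9, 20)), 0, 1, moved)
  direct <- project_grid(hm, moved, min_hit_fraction = 0)
  virt <- project_grid(hm, soup, min_hit_fraction = 0, mesh_transform = tr)
  expect_identical(direct$hit_mask, virt$hit_mask)
  expect_equal(direct$points, virt$points, tolerance = 1e-9)
})
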