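test_that("sheet geometry has the expected counts, extent and area", {
  g0 <- build_sheet_geometry(2, 2, 0.1)
  expect_equal(nrow(g0$nodes), 4)
  expect_equal(nrow(g0$elements), 2)
  expect_equal(apply(g0$nodes, 2, max), c(0.1, 0.1, 0), ignore_attr = TRUE)

  g <- build_sheet_geometry(81, 81, 0.025)
  expect_equal(nrow(g$nodes), 6561)
  expect_equal(max(g$nodes[, 1]), 2)
  expect_equal(max(g$nodes[, 2]), 2)

  g2 <- build_sheet_geometry(41, 41, 0.025)
  expect_equal(surface_area(g2), 40 * 40 * 0.025^2)

  expect_error(build_sheet_geometry(1, 5, 0.1), "nx")
  expect_error(build_sheet_geometry(5, 5, 0), "spacing")
})

test_that("shell geometry is a watertight sphere with correct area", {
  sh <- build_shell_geometry(1.9, 3)
  expect_true(is_watertight(sh))
  el <- sh$elements
  edges <- unique(cbind(pmin(rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])[, 1],
                             rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])[, 2]),
                        pmax(rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])[, 1],
                             rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])[, 2])))
  euler <- nrow(sh$nodes) - nrow(edges) + nrow(el)
  expect_equal(euler, 2)
  expect_lt(max(abs(sqrt(rowSums(sh$nodes^2)) - 1.9)), 1e-6)

  sh4 <- build_shell_geometry(1.0, 4)
  expect_lt(abs(surface_area(sh4) - 4 * pi) / (4 * pi), 0.02)
  # outward orientation: positive signed volume
  p1 <- sh4$nodes[sh4$elements[, 1], ]
  p2 <- sh4$nodes[sh4$elements[, 2], ]
  p3 <- sh4$nodes[sh4$elements[, 3], ]
  vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
             p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  expect_gt(vol, 0)
})

test_that("basket placement follows the contact rules", {
  sh <- build_shell_geometry(2.4, 4)
  bg <- place_basket_array(sh, c(0, 0, 0), contact = "good")
  expect_equal(length(bg$labels), 64)
  expect_setequal(bg$labels[1:8], paste0(LETTERS[1:8], 1))
  h <- mapeval:::mean_edge_length(sh)
  expect_true(all(abs(bg$contact_distance - 0.05) < h))
  # recomputed point-to-node distance matches the stored one
  d <- sqrt(rowSums((bg$positions - sh$nodes[bg$nearest_node, ])^2))
  expect_equal(d, bg$contact_distance, tolerance = 1e-12)

  bp <- place_basket_array(sh, c(0, 0, 0), contact = "poor")
  # concentric: sphere radius 1.9, surface at 2.4 -> midpoint ~0.25 cm out
  expect_true(all(abs(bp$contact_distance - 0.25) < 0.01))
  # collinearity: electrode on the segment sphere-point -> nearest node
  sp <- mapeval:::basket_sphere_points(c(0, 0, 0), 3.8)
  nn_check <- apply(sp$points, 1, function(p) {
    d2 <- rowSums(sweep(sh$nodes, 2, p)^2)
    which.min(d2)
  })
  expect_equal(nn_check, bp$nearest_node)  # exhaustive nearest-node search
  mid <- (sp$points + sh$nodes[nn_check, ]) / 2
  expect_lt(max(abs(mid - bp$positions)), 1e-9)

  # near-pole rows lack full rings even with azimuthal wrap
  st <- surface_projection_stats(bp, sh)
  expect_equal(sum(!is.na(st$mean_neighbor_projection_distance)), 48)
  expect_true(all(is.na(st$mean_neighbor_projection_distance[1:8])))
})

test_that("uniform array placement and projection stats match closed forms", {
  g <- build_sheet_geometry(41, 41, 0.05)
  ua <- place_uniform_array(g, c(1, 1, 0))
  expect_equal(length(ua$labels), 36)
  expect_true(all(abs(ua$positions[, 3] - 0.05) < 1e-12))
  expect_equal(diff(range(ua$positions[, 1])), 2)
  expect_equal(diff(range(ua$positions[, 2])), 2)
  n_interior <- sum(!vapply(ua$adjacency, is.null, logical(1)))
  expect_equal(n_interior, 16)  # (6 - 2)^2

  st <- surface_projection_stats(ua, g)
  inner <- st$mean_neighbor_projection_distance
  expect_equal(unique(round(inner[!is.na(inner)], 9)),
               round(0.4 * (4 + 4 * sqrt(2)) / 8, 9))
  # electrode directly over a node projects at distance equal to standoff
  expect_true(all(abs(st$distance_to_surface - 0.05) < 1e-12))

  # plain 8x8 grid (no wrap): (8-2)^2 = 36 interior, 28 border
  arr8 <- electrode_array(paste0("e", 1:64),
                          cbind(rep(1:8, each = 8) * 0.2,
                                rep(1:8, times = 8) * 0.2, 0.05),
                          c(8, 8), wrap_cols = FALSE,
                          nearest_node = rep(1L, 64),
                          contact_distance = rep(0, 64))
  expect_equal(sum(!vapply(arr8$adjacency, is.null, logical(1))), 36)
})

test_that("projection stats are invariant under node relabeling", {
  g <- build_sheet_geometry(21, 21, 0.1)
  ua <- place_uniform_array(g, c(1, 1, 0), rows = 4, cols = 4, pitch = 0.3)
  st <- surface_projection_stats(ua, g)
  # permute the mesh nodes and rebuild
  set.seed(42)
  perm <- sample(nrow(g$nodes))
  inv <- order(perm)
  g2 <- tissue_geometry(g$nodes[perm, ],
                        matrix(inv[g$elements], ncol = 3),
                        inv[g$surface_nodes], g$surface_normals[perm, ])
  ua2 <- ua
  ua2$nearest_node <- inv[ua$nearest_node]
  st2 <- surface_projection_stats(ua2, g2)
  expect_equal(st$distance_to_surface, st2$distance_to_surface)
  expect_equal(st$mean_neighbor_projection_distance,
               st2$mean_neighbor_projection_distance)
})

test_that("mesh and electrode tables round-trip through their formats", {
  g <- build_sheet_geometry(5, 4, 0.1)
  tmp <- withr::local_tempdir()
  write_mesh_vtk(g, file.path(tmp, "m.vtk"))
  g2 <- read_mesh_vtk(file.path(tmp, "m.vtk"))
  expect_equal(g2$nodes, g$nodes, ignore_attr = TRUE)
  expect_equal(g2$elements, g$elements, ignore_attr = TRUE)

  write_mesh_tables(g, file.path(tmp, "m"))
  g3 <- read_mesh_tables(file.path(tmp, "m"))
  expect_equal(g3$nodes, g$nodes, ignore_attr = TRUE, tolerance = 1e-12)

  ua <- place_uniform_array(g, c(0.2, 0.15, 0), rows = 2, cols = 2,
                            pitch = 0.1)
  write_electrode_table(ua, file.path(tmp, "e.csv"))
  ua2 <- read_electrode_table(file.path(tmp, "e.csv"), grid_shape = c(2, 2),
                              geom = g)
  expect_equal(ua2$positions, ua$positions, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(ua2$labels, ua$labels)
  expect_equal(ua2$nearest_node, ua$nearest_node)
})
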