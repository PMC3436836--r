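# structure / grid I/O, surface construction, property mapping

make_three_residue_pdb <- function(path) {
  atom_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")
  res <- c("LYS", "ALA", "GLU")
  lines <- character(0)
  serial <- 0
  for (i in 1:3) for (a in atom_names) {
    serial <- serial + 1
    lines <- c(lines, pdb_line(serial, a, res[i], "A", i,
                               3.8 * i + serial * 0.05, serial * 0.1, 0,
                               substr(a, 1, 1)))
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("read_pdb parses records, models, altlocs and rejects waters", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_three_residue_pdb(path)
  st <- read_pdb(path)
  expect_s3_class(st, "ProteinStructure")
  expect_equal(nrow(st$atoms), 24)
  expect_equal(unname(nchar(st$sequence["A"])), 3)
  expect_equal(unname(st$sequence["A"]), "KAE")

  # only MODEL 1 is read
  two_models <- c("MODEL        1",
                  pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
                  "ENDMDL", "MODEL        2",
                  pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, "C"),
                  pdb_line(3, "CB", "ALA", "A", 1, 9, 9, 9, "C"),
                  "ENDMDL", "END")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_models, p2)
  st2 <- read_pdb(p2)
  expect_equal(nrow(st2$atoms), 1)
  expect_equal(st2$atoms$x, 0)

  # altLoc resolved to highest occupancy
  alt <- c(pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0, "C", altloc = "A",
                    occ = 0.3),
           pdb_line(2, "CA", "ALA", "A", 1, 2, 0, 0, "C", altloc = "B",
                    occ = 0.7))
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, p3)
  st3 <- read_pdb(p3)
  expect_equal(nrow(st3$atoms), 1)
  expect_equal(st3$atoms$x, 2)

  # water-only file is an empty-structure error
  p4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0, "O",
                      record = "HETATM"), p4)
  expect_error(read_pdb(p4), "no non-water atoms")
  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")))
})

test_that("read_dx parses hand-written grids and round-trips with write_dx", {
  # 2x2x2 grid, values 0..7 in z-fastest file order
  dx <- c("object 1 class gridpositions counts 2 2 2",
          "origin 0.0 0.0 0.0",
          "delta 1.0 0.0 0.0", "delta 0.0 1.0 0.0", "delta 0.0 0.0 1.0",
          "object 2 class gridconnections counts 2 2 2",
          "object 3 class array type double rank 0 items 8 data follows",
          "0 1 2", "3 4 5", "6 7")
  p <- withr::local_tempfile(fileext = ".dx")
  writeLines(dx, p)
  g <- read_dx(p)
  expect_equal(g$counts, c(2L, 2L, 2L))
  expect_equal(g$values[2, 2, 2], 7)
  expect_equal(g$values[1, 1, 2], 1)  # z varies fastest on disk
  expect_equal(g$values[2, 1, 1], 4)  # x varies slowest on disk

  # missing delta -> unsupported grid
  p2 <- withr::local_tempfile(fileext = ".dx")
  writeLines(dx[-3], p2)
  expect_error(read_dx(p2), "delta")

  # sheared delta -> unsupported grid
  dx3 <- dx
  dx3[3] <- "delta 1.0 0.2 0.0"
  p3 <- withr::local_tempfile(fileext = ".dx")
  writeLines(dx3, p3)
  expect_error(read_dx(p3), "sheared")

  # random round trip
  set.seed(42)
  g0 <- scalar_grid(c(-1, 2, 0.5), c(0.5, 1, 0.75),
                    array(rnorm(4 * 3 * 5), c(4, 3, 5)))
  p4 <- withr::local_tempfile(fileext = ".dx")
  write_dx(g0, p4)
  g1 <- read_dx(p4)
  expect_equal(g1$origin, g0$origin, tolerance = 1e-6)
  expect_equal(g1$values, g0$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("build_surface produces closed meshes with correct area", {
  st <- one_atom_structure("C")
  mesh <- build_surface(st)
  r <- 1.7 + 1.4
  expect_lt(abs(sum(mesh$triangle_area) - 4 * pi * r^2) / (4 * pi * r^2),
            0.05)
  expect_true(all(abs(sqrt(rowSums(mesh$triangle_normal^2)) - 1) < 1e-6))
  # outward normals on a sphere point along the radial direction
  expect_true(all(rowSums(mesh$triangle_normal * mesh$triangle_centroid) > 0))

  # closed surface: every edge shared by exactly 2 triangles, Euler = 2
  comp <- mesh_components(mesh)
  expect_equal(length(unique(comp)), 1)
  expect_equal(euler_characteristic(mesh, seq_len(nrow(mesh$triangles))), 2)

  # area converges as spacing decreases
  finer <- build_surface(st, grid_spacing = 0.4)
  err <- function(m) abs(sum(m$triangle_area) - 4 * pi * r^2)
  expect_lt(err(finer), err(mesh))

  # two far-separated atoms give two components, each closed
  at2 <- rbind(st$atoms, transform(st$atoms, serial = 2L, x = 30))
  st2 <- toy_structure(at2)
  mesh2 <- build_surface(st2)
  comp2 <- mesh_components(mesh2)
  expect_equal(length(unique(comp2)), 2)
  for (cid in unique(comp2))
    expect_equal(euler_characteristic(mesh2, which(comp2 == cid)), 2)

  # degenerate: coincident atoms
  at3 <- rbind(st$atoms, transform(st$atoms, serial = 2L))
  expect_error(build_surface(toy_structure(at3)), "degenerate")
})

test_that("mesh adjacency is symmetric and interior edges are shared by 2", {
  mesh <- build_surface(one_atom_structure("C"))
  for (t1 in sample(seq_along(mesh$neighbors), 50))
    for (t2 in mesh$neighbors[[t1]])
      expect_true(t1 %in% mesh$neighbors[[t2]])
  ed <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
              mesh$triangles[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("map_grid_to_surface matches the trilinear oracle", {
  mesh <- icosphere(2, 3)
  # constant grid
  gc <- scalar_grid(c(-6, -6, -6), c(1.5, 1.5, 1.5),
                    array(7.5, c(9, 9, 9)))
  m1 <- map_grid_to_surface(mesh, gc, channel_name = "c")
  expect_equal(m1$channels$c, rep(7.5, nrow(mesh$triangles)))

  # linear field f(x,y,z) = x reproduced exactly at the probe point
  xs <- seq(-6, 6, 1.5)
  gl <- scalar_grid(c(-6, -6, -6), c(1.5, 1.5, 1.5),
                    array(rep(xs, 9 * 9), c(9, 9, 9)))
  m2 <- map_grid_to_surface(mesh, gl, offset = 1, channel_name = "lin")
  probe <- mesh$triangle_centroid + mesh$triangle_normal
  expect_lt(max(abs(m2$channels$lin - probe[, 1])), 1e-9)

  # random grid vs independent oracle at 100 random probe points
  set.seed(7)
  gr <- scalar_grid(c(-6, -6, -6), c(1.5, 1.5, 1.5),
                    array(rnorm(9^3), c(9, 9, 9)))
  pts <- matrix(runif(300, -5, 5), 100, 3)
  got <- mtdminer:::trilinear(gr, pts)$values
  want <- apply(pts, 1, function(p) trilinear_oracle(gr, p))
  expect_lt(max(abs(got - want)), 1e-12)

  # geometry untouched by mapping
  expect_identical(m2$vertices, mesh$vertices)
  expect_identical(m2$triangles, mesh$triangles)

  # disjoint grid is a mapping error; partial overlap only warns
  gfar <- scalar_grid(c(100, 100, 100), c(1, 1, 1), array(0, c(3, 3, 3)))
  expect_error(map_grid_to_surface(mesh, gfar), "disjoint")
  ghalf <- scalar_grid(c(0, -6, -6), c(1.5, 1.5, 1.5),
                       array(1, c(9, 9, 9)))
  expect_warning(map_grid_to_surface(mesh, ghalf, channel_name = "h"),
                 "clamped")
})

test_that("hydrophobicity and H-bond channels follow the built-in tables", {
  st <- make_toy_structure(4, "IRGA", seed = 2)
  mesh <- build_surface(st)
  mesh <- map_hydrophobicity(mesh, st)
  kd <- mesh$channels$hyd
  expect_setequal(unique(kd), c(4.5, -4.5, -0.4, 1.8))
  expect_equal(unique(kd[mesh$triangle_residue == "ILE"]), 4.5)
  expect_equal(unique(kd[mesh$triangle_residue == "ARG"]), -4.5)

  mesh <- map_hbond(mesh, st)
  hb <- mesh$channels$hbond
  expect_true(all(hb %in% c(0, 1)))
  at <- st$atoms[mesh$triangle_atom, ]
  # Ala CB (carbon) is never a donor/acceptor; backbone O always is
  expect_true(all(hb[at$name == "CB"] == 0))
  expect_true(all(hb[at$name == "O"] == 1))
  expect_true(all(hb[at$name == "N"] == 1))
  expect_true(all(hb[at$name == "CA"] == 0))
})

test_that("coulomb_grid matches the screened Coulomb closed form", {
  # single +1 charge (LYS NZ), no screening: phi = 1/(4 pi eps d)
  st <- one_atom_structure("N", residue = "LYS", name = "NZ")
  g <- coulomb_grid(st, spacing = 2, padding = 6,
                    ionic_screening_length = Inf, dielectric = 1)
  idx <- which(g$values == max(g$values), arr.ind = TRUE)
  pts <- expand.grid(x = g$origin[1] + g$spacing[1] * (seq_len(g$counts[1]) - 1),
                     y = g$origin[2] + g$spacing[2] * (seq_len(g$counts[2]) - 1),
                     z = g$origin[3] + g$spacing[3] * (seq_len(g$counts[3]) - 1))
  d <- pmax(sqrt(pts$x^2 + pts$y^2 + pts$z^2), 1)
  # grid values are stored x-fastest, matching expand.grid order
  expect_lt(max(abs(as.vector(g$values) - 1 / (4 * pi * d))), 1e-6)

  # charge-free structure -> all zero
  g0 <- coulomb_grid(one_atom_structure("C", "ALA", "CB"), spacing = 3)
  expect_true(all(g0$values == 0))

  # mirror symmetry: mirrored structure gives mirrored grid
  at <- data.frame(serial = 1:2, name = c("NZ", "CB"),
                   residue_name = c("LYS", "ALA"), chain = "A",
                   residue_seq = 1:2, x = c(2, -1), y = 0, z = 0,
                   element = c("N", "C"), stringsAsFactors = FALSE)
  atm <- transform(at, x = -x)
  gA <- coulomb_grid(toy_structure(at), spacing = 1, padding = 5)
  gB <- coulomb_grid(toy_structure(atm), spacing = 1, padding = 5)
  expect_lt(max(abs(gA$values - gB$values[rev(seq_len(gB$counts[1])), , ])),
            1e-9)
})

test_that("OFF meshes round-trip", {
  mesh <- icosphere(1, 2)
  p <- withr::local_tempfile(fileext = ".off")
  write_off(mesh, p)
  back <- read_off(p)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(back$triangles, mesh$triangles, ignore_attr = TRUE)
})
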