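# trajectory containers and file formats

test_that("topology enforces atom uniqueness and computes molar masses", {
  top <- topology(atom_id = 1:4, atom_type = c("O", "H", "O", "H"),
                  mass = c(16, 1, 16, 1), molecule_id = c(1, 1, 2, 2),
                  molecule_name = "OH")
  expect_equal(unname(molar_masses(top)), 17)
  expect_error(topology(c(1, 1), c("a", "b"), c(1, 1), c(1, 2), "m"),
               "unique")
  # same name, different composition -> caught
  bad <- topology(1:3, c("O", "H", "O"), c(16, 1, 18),
                  molecule_id = c(1, 1, 2), molecule_name = "w")
  expect_error(molar_masses(bad), "differ in molar mass")
})

test_that("trajectory constructor validates shape, times and box", {
  co <- array(0, c(2, 3, 3))
  expect_error(trajectory(co, rep(-1, 3), c(0, 1)), "positive")
  expect_error(trajectory(co, rep(10, 3), c(1, 1)), "strictly increasing")
  tr <- trajectory(co, rep(10, 3), c(0, 1))
  expect_equal(n_frames(tr), 2)
  expect_equal(n_atoms(tr), 3)
})

test_that("one-frame LAMMPS dump reads back the written coordinates", {
  path <- withr::local_tempfile(fileext = ".dump")
  writeLines(c("ITEM: TIMESTEP", "0",
               "ITEM: NUMBER OF ATOMS", "1",
               "ITEM: BOX BOUNDS pp pp pp",
               "0 10", "0 10", "0 10",
               "ITEM: ATOMS id type x y z",
               "1 1 1.0 2.0 3.0"), path)
  tr <- read_lammps_dump(path)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$coords[1, 1, ], c(1, 2, 3))
  expect_equal(tr$box[1, ], rep(10, 3))
})

test_that("scaled dump coordinates are converted through the box length", {
  path <- withr::local_tempfile(fileext = ".dump")
  writeLines(c("ITEM: TIMESTEP", "0",
               "ITEM: NUMBER OF ATOMS", "1",
               "ITEM: BOX BOUNDS pp pp pp",
               "0 20", "0 20", "0 20",
               "ITEM: ATOMS id type xs ys zs",
               "1 1 0.5 0.25 0.75"), path)
  tr <- read_lammps_dump(path)
  expect_equal(tr$coords[1, 1, ], c(10, 5, 15))
})

test_that("LAMMPS write -> read round-trips and normalizes atom order", {
  tr <- generate_brownian_trajectory(5, true_D = 0.02, dt = 1, n_frames = 4,
                                     box = 12, seed = 11)
  path <- withr::local_tempfile(fileext = ".dump")
  write_lammps_dump(tr, path)
  back <- read_lammps_dump(path)
  expect_equal(back$coords, tr$coords, tolerance = 1e-6)
  expect_equal(back$box, tr$box)

  # shuffle atom lines within each frame: reader must restore id order
  lines <- readLines(path)
  atoms_hdr <- grep("^ITEM: ATOMS", lines)
  for (h in atoms_hdr) {
    rows <- (h + 1):(h + 5)
    lines[rows] <- lines[sample(rows)]
  }
  shuffled <- withr::local_tempfile(fileext = ".dump")
  writeLines(lines, shuffled)
  expect_equal(read_lammps_dump(shuffled)$coords, tr$coords, tolerance = 1e-6)
})

test_that("malformed and varying-count dumps raise structural errors", {
  path <- withr::local_tempfile(fileext = ".dump")
  writeLines(c("ITEM: TIMESTEP", "0",
               "ITEM: NUMBER OF ATOMS", "2",
               "ITEM: BOX BOUNDS pp pp pp", "0 10", "0 10", "0 10",
               "ITEM: ATOMS id type x y z",
               "1 1 0 0 0"), path)
  expect_error(read_lammps_dump(path), "declares 2 atoms")
  path2 <- withr::local_tempfile(fileext = ".dump")
  writeLines(c("ITEM: TIMESTEP", "0",
               "ITEM: NUMBER OF ATOMS", "1",
               "ITEM: BOX BOUNDS xy xz yz pp pp pp",
               "0 10 0", "0 10 0", "0 10 0",
               "ITEM: ATOMS id type x y z",
               "1 1 0 0 0"), path2)
  expect_error(read_lammps_dump(path2), "triclinic")
})

test_that("extended-XYZ round-trips species and coordinates", {
  co <- array(c(1, 4, 2, 5, 3, 6), c(1, 2, 3))
  tr <- trajectory(co, rep(10, 3), 0)
  tr$species <- c("Si", "O")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(tr, path)
  back <- read_extxyz(path)
  expect_identical(back$species, c("Si", "O"))
  expect_equal(back$coords, tr$coords, tolerance = 1e-6)
  expect_equal(back$box[1, ], rep(10, 3))
})

test_that("extended-XYZ preserves frame count and rejects bad input", {
  tr <- generate_brownian_trajectory(3, 0.01, 1, 100, 15, seed = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(tr, path)
  expect_equal(n_frames(read_extxyz(path)), 100)

  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_extxyz(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", 'Lattice="10 1 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3',
               "X 0 0 0"), bad)
  expect_error(read_extxyz(bad), "non-orthogonal")
  nolat <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "no lattice here", "X 0 0 0"), nolat)
  expect_error(read_extxyz(nolat), "Lattice")
})

test_that("thermo tables resolve aliases and flag non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Temp,Press", "0,450,100", "1,450,101", "2,450,99"), path)
  ts <- read_thermo_table(path)
  expect_s3_class(ts, "thermo_series")
  expect_equal(nrow(ts), 3)
  expect_equal(mean(ts$T), 450)
  expect_null(ts$V)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,T", "0,450", "1,oops"), path2)
  expect_error(read_thermo_table(path2), "row 2")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,Press", "0,100"), path3)
  expect_error(read_thermo_table(path3), "temperature")
})

test_that("topology files load with site flags and reject missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# donor/acceptor flags mark H-bond sites",
               paste("atom_id", "atom_type", "mass", "molecule_id",
                     "molecule_name", "donor", "acceptor", sep = "\t"),
               paste(1, "O_Z", 16, 1, "api", "FALSE", "TRUE", sep = "\t"),
               paste(2, "H_Z2", 1, 1, "api", "TRUE", "FALSE", sep = "\t")),
             path)
  top <- read_topology(path)
  expect_s3_class(top, "topology")
  expect_identical(top$acceptor, c(TRUE, FALSE))
  expect_equal(unname(molar_masses(top)), 17)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("atom_id\tmass", "1\t16"), bad)
  expect_error(read_topology(bad), "required columns")
})

test_that("thermal scans round-trip through their TSV form with truth", {
  sc <- generate_thermal_scan(scan_truth(), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_thermal_scan(sc, path)
  back <- read_thermal_scan(path)
  expect_equal(back$T, sc$T)
  expect_equal(back$rho, sc$rho, tolerance = 1e-12)
  expect_equal(attr(back, "truth")$true_Tg, 350)
})
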