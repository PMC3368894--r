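test_that("atom typing covers the 167 standard heavy atoms uniquely", {
  tab <- atom_type_table()
  protein <- tab$map[tab$map$resname != "HOH", ]
  expect_equal(nrow(protein), 167)
  expect_false(anyDuplicated(paste(protein$resname, protein$atom)) > 0)
  expect_true(all(protein$type >= 1 & protein$type <= 30))
  # spot checks against the published typing table
  lookup <- function(rn, at) {
    r <- tab$map[tab$map$resname == rn & tab$map$atom == at, ]
    c(r$type, tab$types$radius[r$type])
  }
  expect_equal(lookup("GLY", "CA"), c(13, 1.87))
  expect_equal(lookup("LYS", "NZ"), c(26, 1.50))
  expect_equal(lookup("HOH", "O"), c(31, 1.40))
  expect_equal(tab$types$radius[4], 1.40)   # backbone O
})

test_that("PDB parsing keeps heavy atoms, waters on request, flags issues", {
  tc <- tiny_complex()
  f <- tempfile(fileext = ".pdb")
  write_structure(tc$complexed, f)
  st <- parse_structure(f)
  expect_equal(n_atoms(st), n_atoms(tc$complexed))
  # round trip at PDB precision (3 decimal places)
  expect_close(coords(st), coords(tc$complexed), 1e-3 + 1e-9)
  # chain selection and the missing-chain error
  stA <- parse_structure(f, chains = "A")
  expect_setequal(unique(stA$atoms$chain), "A")
  expect_error(parse_structure(f, chains = "Z"), "chain")

  water_pdb <- paste(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END", sep = "\n")
  st2 <- assign_atom_types(parse_structure(water_pdb, keep_water = TRUE))
  expect_equal(sum(st2$atoms$type == 31, na.rm = TRUE), 1)
  st3 <- parse_structure(water_pdb)
  expect_equal(n_atoms(st3), 3)

  h_only <- paste(
    "ATOM      1  H   GLY A   1       0.000   0.000   0.000  1.00  0.00           H",
    "END", sep = "\n")
  expect_warning(st4 <- parse_structure(h_only), "no heavy atoms")
  expect_equal(n_atoms(st4), 0)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  alt_pdb <- paste(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       9.000   0.000   0.000  0.60  0.00           N",
    "END", sep = "\n")
  st <- parse_structure(alt_pdb)
  expect_equal(n_atoms(st), 1)
  expect_equal(st$atoms$x, 9.0)
})

test_that("unknown residues are flagged untyped, never silently typed", {
  st <- ppi_structure(data.frame(chain = "A", resno = 1, resname = "XYZ",
                                 atom = "C1", x = 0, y = 0, z = 0))
  expect_warning(st <- assign_atom_types(st), "untyped")
  expect_true(is.na(st$atoms$type))
})

test_that("SASA matches the closed form, buries enclosed atoms, and agrees
           with a Monte-Carlo sphere oracle", {
  lone <- assign_atom_types(ppi_structure(data.frame(
    chain = "A", resno = 1, resname = "GLY", atom = "CA",
    x = 0, y = 0, z = 0)))
  expect_equal(compute_sasa(lone), 4 * pi * (1.87 + 1.4)^2, tolerance = 1e-12)

  # an atom enclosed by a tight shell of atoms has zero accessible area
  sh <- sphere_points(60) * 3.0
  shell <- data.frame(chain = "A", resno = seq_len(61) + 1, resname = "ALA",
                      atom = "CB", x = c(0, sh[, 1]), y = c(0, sh[, 2]),
                      z = c(0, sh[, 3]))
  shell$resno[1] <- 1
  buried <- assign_atom_types(ppi_structure(shell))
  expect_equal(compute_sasa(buried)[1], 0)

  # overlapping cluster vs a random-point Monte-Carlo oracle (2% criterion)
  clus <- assign_atom_types(ppi_structure(data.frame(
    chain = "A", resno = 1:3, resname = "ALA", atom = "CB",
    x = c(0, 2.5, 1.0), y = c(0, 0, 2.2), z = 0)))
  got <- compute_sasa(clus, points = 960)
  mc_oracle <- function(xyz, radii, probe = 1.4, n = 20000) {
    set.seed(42)
    vapply(seq_len(nrow(xyz)), function(i) {
      r <- radii[i] + probe
      p <- matrix(stats::rnorm(3 * n), ncol = 3)
      p <- p / sqrt(rowSums(p^2)) * r
      p <- sweep(p, 2, as.numeric(xyz[i, ]), "+")
      free <- rep(TRUE, n)
      for (j in setdiff(seq_len(nrow(xyz)), i)) {
        free <- free & (rowSums(sweep(p, 2, as.numeric(xyz[j, ]))^2) >
                          (radii[j] + probe)^2)
      }
      4 * pi * r^2 * mean(free)
    }, numeric(1))
  }
  want <- mc_oracle(coords(clus), clus$atoms$radius)
  expect_true(all(abs(got - want) / want < 0.02))
})

test_that("SASA is invariant under rigid motion with a co-rotated point set", {
  st <- assign_atom_types(tiny_complex()$unbound$A)
  R <- fixed_rotation()
  base <- compute_sasa(st, points = 480)
  rot <- compute_sasa(transform_structure(st, R, c(3, -2, 7)),
                      points = 480, orient = R)
  expect_close(rot, base, 1e-6 * max(base))
})

test_that("dSASA labelling follows the buried-fraction definition and is
           monotone in the partner", {
  tc <- tiny_complex()
  lab <- label_ppi_atoms(tc$unbound$A, tc$complexed, points = 480)
  a <- lab$atoms
  surf <- !is.na(a$dsasa)
  expect_true(all(a$dsasa[surf] >= 0 & a$dsasa[surf] <= 1))
  expect_identical(a$is_ppi[surf], a$dsasa[surf] > 0)
  expect_true(all(is.na(a$dsasa[!a$is_surface])))
  expect_close(a$dsasa[surf],
               pmin(1, pmax(0, (a$sasa_u - a$sasa_c)[surf] / a$sasa_u[surf])),
               1e-12)

  # removing partner atoms never increases any atom's dSASA
  partB <- tc$complexed
  keep <- partB$atoms$chain == "A" |
    partB$atoms$resno <= stats::median(partB$atoms$resno)
  partB$atoms <- partB$atoms[keep, ]
  lab_part <- label_ppi_atoms(tc$unbound$A, partB, points = 480)
  expect_true(all(lab_part$atoms$dsasa[surf] <= a$dsasa[surf] + 1e-12))

  # total buried area is non-negative
  expect_gte(sum((a$sasa_u - a$sasa_c)[surf]), 0)

  bad <- tc$complexed
  bad$atoms <- bad$atoms[-1, ]
  expect_error(label_ppi_atoms(tc$unbound$A, bad), "missing")
})

test_that("prediction-eligible atoms are mid-chain surface protein atoms", {
  p <- tiny_prep()
  a <- p$structure$atoms
  sel <- isTRUE_vec(a$is_predictable)
  expect_true(all(a$sasa_u[sel] > 0))
  expect_true(all(a$type[sel] %in% 1:30))
  # chain termini have incomplete phi/psi and are excluded
  expect_false(any(a$resno[sel] == min(a$resno)))
  expect_false(any(a$resno[sel] == max(a$resno)))
  # buried atoms are excluded, mid-chain surface atoms are kept
  mid <- a$resno > min(a$resno) & a$resno < max(a$resno)
  expect_false(any(sel & a$sasa_u == 0))
  expect_true(any(sel[mid & a$sasa_u > 0]))
})
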