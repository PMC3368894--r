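test_that("occupancy marks van der Waals volume correctly", {
  st <- assign_atom_types(ppi_structure(data.frame(
    chain = "A", resno = 1:2, resname = "ALA", atom = "CB",
    x = c(0, 40), y = 0, z = 0)))
  grid <- grid_for_structure(st, spacing = 1, margin = 8)
  occ <- compute_occupancy(st, grid)
  at_center <- cells_in_sphere(grid, c(0, 0, 0), 0.8)
  expect_true(all(occ[at_center]))
  far <- cells_in_sphere(grid, c(20, 0, 0), 1.5)
  expect_false(any(occ[far]))
})

test_that("occupied fraction matches a Monte-Carlo volume oracle within 3%", {
  st <- assign_atom_types(tiny_complex()$unbound$A)
  grid <- grid_for_structure(st, spacing = 1, margin = 10)
  occ <- compute_occupancy(st, grid)
  center <- colMeans(coords(st))
  idx <- cells_in_sphere(grid, center, 10)
  got <- sum(occ[idx]) / length(idx)
  set.seed(7)
  n <- 1e5
  p <- matrix(stats::rnorm(3 * n), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * stats::runif(n)^(1 / 3) * 10
  p <- sweep(p, 2, center, "+")
  xyz <- coords(st)
  rad <- st$atoms$radius
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(xyz)))
    inside <- inside | rowSums(sweep(p, 2, xyz[i, ])^2) <= rad[i]^2
  expect_lt(abs(got - mean(inside)), 0.03)
})

test_that("a single identity-frame atom reproduces its canonical histogram", {
  kb <- tiny_kb()
  # pick a populated (center, partner) pair
  tt <- which(kb$totals > 0, arr.ind = TRUE)[1, ]
  t0 <- tt[1]
  # three-atom construction with an exact identity local frame at atom 1
  tab <- atom_type_table()
  st <- ppi_structure(data.frame(
    chain = "A", resno = c(1, 2, 2), resname = "ALA",
    atom = c("CB", "CB", "CA"),
    x = c(0, 1.5, 1.5), y = c(0, 0, 1.5), z = 0))
  st <- assign_atom_types(st)
  st$atoms$type[1] <- t0
  st$atoms$radius[1] <- tab$types$radius[t0]
  st$atoms$sasa_u <- c(1, 0, 0)   # only the probe atom contributes
  st$atoms$is_surface <- st$atoms$sasa_u > 0
  fr <- build_local_frame(st, 1)
  expect_close(fr$R, diag(3), 1e-12)
  # grid aligned so canonical cell centres land exactly on grid centres
  grid <- grid_spec(origin = c(-20, -20, -20), spacing = 1, dims = c(40, 40, 40))
  pd <- suppressWarnings(project_pdms(st, kb, grid, mode = "nearest",
                                      mask = FALSE))
  for (j in which(kb$totals[t0, ] > 0)) {
    h <- kb_histogram(kb, t0, j)
    got <- pd$values[, , , j] * pd$n_contributing
    idx <- cbind(floor(h$x + 20) + 1, floor(h$y + 20) + 1,
                 floor(h$z + 20) + 1)
    expect_close(got[idx], h$mass, 1e-8)
    expect_equal(sum(got), sum(h$mass), tolerance = 1e-8)
  }
})

test_that("projection is linear in the contributing atoms before averaging", {
  kb <- tiny_kb()
  tc <- tiny_complex()
  st <- add_sasa(assign_atom_types(tc$unbound$A), points = 240)
  grid <- grid_for_structure(st)
  sub <- function(keep) {
    s2 <- st
    s2$atoms$sasa_u[!keep] <- 0
    s2$atoms$is_surface <- s2$atoms$sasa_u > 0
    s2
  }
  surf <- st$atoms$is_surface
  half <- surf & seq_len(n_atoms(st)) %% 2 == 0
  other <- surf & !half
  pab <- suppressWarnings(project_pdms(st, kb, grid, mask = FALSE))
  pa <- suppressWarnings(project_pdms(sub(half), kb, grid, mask = FALSE))
  pb <- suppressWarnings(project_pdms(sub(other), kb, grid, mask = FALSE))
  expect_close(pab$values * pab$n_contributing,
               pa$values * pa$n_contributing + pb$values * pb$n_contributing,
               1e-10)
})

test_that("density maps vanish inside the protein and on empty surfaces", {
  kb <- tiny_kb()
  st <- add_sasa(assign_atom_types(tiny_complex()$unbound$A), points = 240)
  grid <- grid_for_structure(st)
  occ <- compute_occupancy(st, grid)
  pd <- suppressWarnings(project_pdms(st, kb, grid, occupancy = occ))
  expect_true(all(pd$values >= 0))
  expect_equal(sum(pd$values[rep(as.logical(occ), 31)]), 0)

  none <- st
  none$atoms$sasa_u <- 0
  none$atoms$is_surface <- FALSE
  pd0 <- project_pdms(none, kb, grid, mask = FALSE)
  expect_equal(sum(pd0$values), 0)
  expect_equal(pd0$n_contributing, 0L)
})

test_that("density maps are rigid-motion equivariant via grid orientation", {
  kb <- tiny_kb()
  st <- add_sasa(assign_atom_types(tiny_complex()$unbound$A), points = 240)
  R <- fixed_rotation()
  st_rot <- transform_structure(st, R, c(4, 5, -6))
  g1 <- grid_for_structure(st, spacing = 1, margin = 8)
  g2 <- grid_for_structure(st_rot, spacing = 1, margin = 8, orientation = R)
  p1 <- suppressWarnings(project_pdms(st, kb, g1, mask = FALSE))
  p2 <- suppressWarnings(project_pdms(st_rot, kb, g2, mask = FALSE))
  expect_equal(g1$dims, g2$dims)
  expect_close(p2$values, p1$values, 1e-6 * max(p1$values))
})

test_that("trilinear splatting conserves each contribution's mass within 1%", {
  kb <- tiny_kb()
  st <- add_sasa(assign_atom_types(tiny_complex()$unbound$A), points = 240)
  grid <- grid_for_structure(st, margin = 12)
  pd <- suppressWarnings(project_pdms(st, kb, grid, mask = FALSE))
  # expected mass: one unit per (contributing atom, populated partner type)
  a <- st$atoms
  frames <- structure_frames(st)
  contrib <- which(!is.na(a$type) & a$type <= 30 & a$sasa_u > 0 &
                     !vapply(frames, is.null, logical(1)))
  expected <- sum(vapply(contrib, function(i)
    sum(kb$totals[a$type[i], ] > 0), numeric(1)))
  expect_lt(abs(sum(pd$values) * pd$n_contributing - expected) / expected,
            0.01)
})

test_that("density maps export as parseable OpenDX text", {
  kb <- tiny_kb()
  st <- add_sasa(assign_atom_types(tiny_complex()$unbound$A), points = 240)
  grid <- grid_for_structure(st)
  pd <- suppressWarnings(project_pdms(st, kb, grid))
  f <- tempfile(fileext = ".dx")
  write_pdm_dx(pd, j = 8, f)
  lines <- readLines(f)
  expect_match(lines[1], "gridpositions counts")
  nums <- as.numeric(unlist(strsplit(
    lines[grep("data follows", lines) + 1], " ")))
  expect_false(any(is.na(nums)))
})
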