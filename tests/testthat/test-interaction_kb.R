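test_that("filter admission follows the value < threshold rule", {
  f <- synthetic_filter_matrix()
  expect_true(filter_admits(f, 8, 8))      # aliphatic side carbons pack
  expect_false(filter_admits(f, 8, 26))    # apolar with charged N rejected
  expect_true(filter_admits(f, 1, 4))      # backbone NH donates to O
  v <- f$values
  expect_true(all(abs(v - t(v)) < 1e-12))
  # explicit threshold semantics
  g <- filter_matrix(matrix(-0.5, 31, 31))
  g$values[2, 3] <- g$values[3, 2] <- -0.05
  expect_true(filter_admits(g, 5, 6))
  expect_false(filter_admits(g, 2, 3))
})

test_that("filter TSV round-trips and bad input errors", {
  f <- synthetic_filter_matrix()
  tsv <- tempfile(fileext = ".tsv")
  write_filter_matrix(f, tsv)
  g <- load_filter_matrix(tsv)
  expect_equal(unname(g$values), unname(f$values))
  expect_error(filter_matrix(matrix(0, 5, 5)), "31x31")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\tx"), bad)
  expect_error(load_filter_matrix(bad))
})

test_that("asymmetric filters are symmetrized by pairwise minimum", {
  v <- matrix(0, 31, 31)
  v[1, 2] <- -0.9
  expect_warning(f <- filter_matrix(v), "symmetrized")
  expect_equal(f$values[2, 1], -0.9)
})

test_that("contact harvesting excludes covalent context and filtered pairs", {
  st <- tiny_refs()[[1]]
  filt <- synthetic_filter_matrix()
  obs <- harvest_contacts(st, filt, strict_interior = FALSE)
  expect_gt(nrow(obs), 0)
  expect_true(all(obs$center_type <= 30))
  # every recorded (center, partner) type pair passes the filter
  expect_true(all(filter_admits(filt, obs$center_type, obs$partner_type)))
  # displacements obey the contact rule upper bound
  tab <- atom_type_table()$types$radius
  dmax <- tab[obs$center_type] + tab[obs$partner_type] + 1.4
  expect_true(all(sqrt(obs$dx^2 + obs$dy^2 + obs$dz^2) <= dmax + 1e-9))

  # a filter rejecting everything yields no observations at any distance
  none <- filter_matrix(matrix(0, 31, 31))
  expect_equal(nrow(harvest_contacts(st, none, strict_interior = FALSE)), 0)

  # brute-force oracle: the observation count equals an independent scan
  # applying every exclusion (same residue, graph distance <= 3, distance
  # rule, filter, protein center with a frame)
  frag <- st
  frag$atoms <- frag$atoms[frag$atoms$resno <= 8, ]
  obs2 <- harvest_contacts(frag, filt, strict_interior = FALSE)
  adj <- bond_graph(frag)
  frames <- structure_frames(frag, adj)
  a <- frag$atoms
  xyz <- coords(frag)
  n_expected <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (i == j) next
    if (a$resno[i] == a$resno[j]) next
    if (j %in% graph_neighbourhood(adj, i, 3)) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) >
        a$radius[i] + a$radius[j] + 1.4) next
    if (!filter_admits(filt, a$type[i], a$type[j])) next
    if (a$type[i] > 30 || is.null(frames[[i]])) next
    n_expected <- n_expected + 1L
  }
  expect_equal(nrow(obs2), n_expected)
})

test_that("local frames are orthonormal, right-handed and rotation-equivariant", {
  st <- assign_atom_types(tiny_complex()$unbound$A)
  adj <- bond_graph(st)
  frames <- structure_frames(st, adj)
  expect_true(all(!vapply(frames, is.null, logical(1))))
  for (fr in frames[seq(1, length(frames), by = 17)]) {
    R <- fr$R
    expect_close(crossprod(R), diag(3), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  for (k in 1:20) {
    R <- random_rotation(seed = 100 + k)
    str2 <- transform_structure(st, R, c(1, 2, 3))
    i <- (7 + 11 * k) %% n_atoms(st) + 1
    f1 <- build_local_frame(st, i, adj)
    f2 <- build_local_frame(str2, i, bond_graph(str2))
    expect_close(f2$R, R %*% f1$R, 1e-8)
  }
})

test_that("histogram accumulation conserves counts and normalizes", {
  one <- data.frame(center_type = 8L, partner_type = 8L,
                    dx = 0.2, dy = -0.3, dz = 1.1, structure = 1L)
  kb1 <- accumulate_histograms(one)
  expect_equal(nrow(kb1$cells), 1)
  expect_equal(kb1$cells$n, 1L)
  expect_equal(kb1$dropped, 0)

  set.seed(3)
  many <- data.frame(center_type = sample(1:30, 500, TRUE),
                     partner_type = sample(1:31, 500, TRUE),
                     dx = stats::runif(500, -6, 6),
                     dy = stats::runif(500, -6, 6),
                     dz = stats::runif(500, -6, 6), structure = 1L)
  kb <- accumulate_histograms(many)
  expect_equal(sum(kb$totals), 500)
  t0 <- many$center_type[1]; j0 <- many$partner_type[1]
  h <- kb_histogram(kb, t0, j0)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)

  far <- data.frame(center_type = 1L, partner_type = 1L,
                    dx = 25, dy = 0, dz = 0, structure = 1L)
  kbf <- accumulate_histograms(rbind(many, far))
  expect_equal(kbf$dropped, 1)
  expect_equal(sum(kbf$totals), 500)
})

test_that("the knowledge base is pose-invariant and scales linearly in data", {
  refs <- tiny_refs()[1:2]
  filt <- synthetic_filter_matrix()
  kb <- build_knowledge_base(refs, filt, strict_interior = FALSE)
  rot <- lapply(refs, transform_structure, R = fixed_rotation(),
                t = c(5, -3, 11))
  kb_rot <- build_knowledge_base(rot, filt, strict_interior = FALSE)
  expect_identical(kb$cells, kb_rot$cells)   # exact cell-wise counts

  kb2 <- build_knowledge_base(c(refs, refs), filt, strict_interior = FALSE)
  expect_equal(kb2$totals, kb$totals * 2L)
  m1 <- kb_histogram(kb, 8, 8)
  m2 <- kb_histogram(kb2, 8, 8)
  expect_equal(m1$mass, m2$mass, tolerance = 1e-12)
})

test_that("admitted type pairs equal a brute-force filter scan", {
  filt <- synthetic_filter_matrix()
  obs <- harvest_contacts(tiny_refs(), filt, strict_interior = FALSE)
  seen <- unique(paste(obs$center_type, obs$partner_type))
  brute <- outer(1:31, 1:31, function(a, b) filt$values[cbind(a, b)] < -0.1)
  for (s in seen) {
    ij <- as.integer(strsplit(s, " ")[[1]])
    expect_true(brute[ij[1], ij[2]])
  }
})

test_that("knowledge bases persist to plain text and back", {
  kb <- tiny_kb()
  d <- tempfile()
  write_kb(kb, d)
  kb2 <- read_kb(d)
  expect_equal(kb2$cells, kb$cells)
  expect_equal(kb2$totals, kb$totals)
  expect_equal(kb2$spacing, kb$spacing)
  expect_equal(kb2$extent, kb$extent)
})
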