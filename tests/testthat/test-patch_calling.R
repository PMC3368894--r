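test_that("confidence tables are true-positive fractions per activity bin", {
  act <- c(rep(0.55, 10), rep(0.95, 4), 1.0)
  lab <- c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 4), TRUE)
  ct <- build_confidence_table(act, lab)
  expect_equal(ct$confidence[6], 0.3)       # 3 of 10 in [0.5, 0.6)
  expect_equal(ct$confidence[10], 1.0)      # activity 1.0 joins the last bin
  expect_equal(ct$count[10], 5)
  # conservation identity, exactly
  expect_equal(sum(ct$confidence[ct$count > 0] * ct$count[ct$count > 0]),
               sum(lab))

  all_pos <- build_confidence_table(c(0.2, 0.6, 0.9), c(TRUE, TRUE, TRUE))
  expect_true(all(all_pos$confidence[all_pos$count > 0] == 1))

  expect_error(build_confidence_table(numeric(0), logical(0)), "no validation")
  expect_error(to_confidence(1.2, ct), "outside")
})

test_that("activity-to-confidence lookup respects bins and monotone tables", {
  ct <- build_confidence_table(seq(0.05, 0.95, 0.1),
                               c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(to_confidence(0.55, ct), ct$confidence[6])
  expect_equal(to_confidence(1.0, ct), ct$confidence[10])
  # property: a monotone table yields monotone confidences of activity
  for (k in 1:5) {
    set.seed(k)
    conf <- sort(stats::runif(10))
    tab <- ct
    tab$confidence <- conf
    a <- sort(stats::runif(50))
    expect_true(all(diff(to_confidence(a, tab)) >= 0))
  }
})

test_that("patch calling matches a brute-force single-linkage oracle", {
  brute_patches <- function(xyz, conf, seed_thr = 0.6, grow = 11,
                            member_thr = 0.2, merge = 10) {
    seeds <- which(conf > seed_thr)
    if (!length(seeds)) return(list())
    # exhaustive pairwise merging to a fixed point
    comps <- as.list(seeds)
    repeat {
      merged <- FALSE
      for (a in seq_along(comps)) {
        for (b in seq_along(comps)) {
          if (b <= a) next
          dmin <- min(as.matrix(stats::dist(xyz))[comps[[a]], comps[[b]]])
          if (dmin <= merge) {
            comps[[a]] <- sort(c(comps[[a]], comps[[b]]))
            comps[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    lapply(comps, function(s) {
      elig <- which(conf > member_thr)
      d <- as.matrix(stats::dist(xyz))
      near <- elig[apply(d[s, elig, drop = FALSE], 2, min) <= grow]
      sort(unique(c(s, near)))
    })
  }
  for (rep in 1:5) {
    set.seed(rep * 31)
    xyz <- matrix(stats::runif(150, 0, 40), ncol = 3)
    conf <- stats::runif(50)
    got <- call_patches(xyz, conf)
    want <- brute_patches(xyz, conf)
    expect_equal(length(got), length(want))
    got_sets <- lapply(got, `[[`, "members")
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("patch calling edge rules: empty, merge at 9 A, order and rigid
           invariance, monotone shrinkage", {
  xyz <- matrix(c(0, 0, 0, 9, 0, 0, 30, 0, 0), ncol = 3, byrow = TRUE)
  expect_length(call_patches(xyz, c(0.5, 0.5, 0.1)), 0)

  two <- call_patches(xyz[1:2, ], c(0.9, 0.9))
  expect_length(two, 1)   # seeds 9 A apart merge

  set.seed(9)
  xyz <- matrix(stats::runif(120, 0, 35), ncol = 3)
  conf <- stats::runif(40)
  base <- call_patches(xyz, conf)
  perm <- sample(40)
  shuffled <- call_patches(xyz[perm, ], conf[perm])
  canon <- function(p, map = seq_len(40)) sort(map[p$members])
  expect_setequal(lapply(shuffled, canon, map = perm),
                  lapply(base, canon))
  R <- fixed_rotation()
  moved <- call_patches(xyz %*% t(R) + 5, conf)
  expect_setequal(lapply(moved, canon), lapply(base, canon))

  hi <- call_patches(xyz, conf, seed_threshold = 0.8)
  expect_lte(length(unique(unlist(lapply(hi, `[[`, "members")))),
             length(unique(unlist(lapply(base, `[[`, "members")))))
})

test_that("residue conversion applies the strict 30% surface-atom rule", {
  atoms <- data.frame(chain = "A",
                      resno = rep(1:3, times = c(10, 10, 4)),
                      resname = "ALA",
                      atom = paste0("C", 1:24), x = stats::runif(24),
                      y = stats::runif(24), z = stats::runif(24))
  st <- ppi_structure(atoms)
  st$atoms$is_surface <- c(rep(TRUE, 20), rep(FALSE, 4))
  # patch containing 4 atoms of residue 1 and 3 atoms of residue 2
  patch <- list(list(seeds = 1L, members = c(1:4, 11:13)))
  calls <- residues_from_patches(patch, st, atom_index = seq_len(24))
  expect_equal(calls$positive[calls$resno == 1], TRUE)    # 0.4 > 0.3
  expect_equal(calls$positive[calls$resno == 2], FALSE)   # 0.3 not > 0.3
  expect_false(3 %in% calls$resno)                        # fully buried

  st$atoms$dsasa <- c(rep(1, 10), rep(c(1, 0), 5), rep(NA, 4))
  truth <- actual_residue_sites(st)
  expect_true(truth$positive[truth$resno == 1])   # fully buried residue
  expect_true(truth$positive[truth$resno == 2])   # 0.5 > 0.3
  # exactly 30% buried is negative under the strict inequality
  st$atoms$dsasa <- c(rep(1, 10), rep(c(1, 1, 1, 0, 0), 2), rep(NA, 4))
  st$atoms$dsasa[14:20] <- 0
  truth <- actual_residue_sites(st)
  expect_equal(truth$fraction[truth$resno == 2], 0.3)
  expect_false(truth$positive[truth$resno == 2])
  st$atoms$dsasa <- NA_real_
  expect_error(actual_residue_sites(st), "dSASA")
})
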