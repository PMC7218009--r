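test_that("neurite_tree enforces structural invariants", {
  good <- tibble::tibble(
    id = 1:2, parent = c(NA, 1L), kind = c("soma", "dendrite"),
    length = c(40, 100), diam_prox = c(40, 4), diam_dist = c(40, 3)
  )
  expect_s3_class(neurite_tree(good), "neurite_tree")
  expect_error(neurite_tree(dplyr::mutate(good, parent = c(NA, 9L))),
               "undefined parent")
  expect_error(neurite_tree(dplyr::mutate(good, length = c(40, 0))),
               "lengths")
  expect_error(neurite_tree(good[2:1, ]), "root|ordered")
  two_soma <- dplyr::bind_rows(good,
    tibble::tibble(id = 3L, parent = 1L, kind = "soma", length = 40,
                   diam_prox = 40, diam_dist = 40))
  expect_error(neurite_tree(two_soma), "exactly one soma")
})

test_that("SWC reader handles a straight dendrite and rejects bad input", {
  f <- tempfile(fileext = ".swc")
  writeLines(c(
    "# comment",
    "1 1 0 0 0 10 -1",
    "2 3 50 0 0 1 1",
    "3 3 100 0 0 1 2"
  ), f)
  tree <- read_swc(f)
  dend <- tree$sections[tree$sections$kind == "dendrite", ]
  expect_equal(nrow(dend), 2)
  expect_equal(sum(dend$length), 100)
  expect_equal(max_dendritic_path(tree), 0.1)
  # hillock + initial segment appended with the fixed geometry
  expect_equal(tree$sections$length[tree$sections$kind == "hillock"], 20)
  expect_equal(tree$sections$diam_dist[tree$sections$kind == "hillock"], 3.3)
  expect_equal(tree$sections$length[tree$sections$kind == "initial_segment"], 30)

  writeLines(c("1 1 0 0 0 10 -1", "2 3 50 0 0 1 7"), f)
  expect_error(read_swc(f), "undefined parent")
  writeLines(c("1 1 0 0 0 10 -1", "2 3 50 0 0"), f)
  expect_error(read_swc(f), "line 2")
})

test_that("SWC writer round-trips topology and section lengths", {
  tree <- synthetic_motoneuron(n_stems = 3, branch_depth = 2, seed = 7)
  f <- tempfile(fileext = ".swc")
  write_swc(tree, f)
  back <- read_swc(f)
  d0 <- tree$sections[tree$sections$kind == "dendrite", ]
  d1 <- back$sections[back$sections$kind == "dendrite", ]
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(sort(d1$length), sort(d0$length), tolerance = 1e-9)
  # parent structure preserved: same multiset of (parent path, own length)
  p0 <- motorunit:::section_path_start(tree)[match(d0$id, tree$sections$id)]
  p1 <- motorunit:::section_path_start(back)[match(d1$id, back$sections$id)]
  expect_equal(sort(round(p0 + d0$length, 6)), sort(round(p1 + d1$length, 6)))
})

test_that("synthetic tree is deterministic and reaches the target path", {
  t1 <- synthetic_motoneuron(seed = 3)
  t2 <- synthetic_motoneuron(seed = 3)
  expect_identical(t1$sections, t2$sections)
  t3 <- synthetic_motoneuron(seed = 4)
  expect_false(identical(t1$sections, t3$sections))

  single <- synthetic_motoneuron(n_stems = 1, branch_depth = 0,
                                 max_path_mm = 1.5, taper_per_mm = 0)
  dend <- single$sections[single$sections$kind == "dendrite", ]
  expect_equal(nrow(dend), 1)
  expect_equal(dend$length, 1500)
  expect_equal(dend$diam_prox, dend$diam_dist)
})

test_that("every D_path band is populated on every stem under defaults", {
  tree <- synthetic_motoneuron()
  s <- tree$sections
  stems <- s$id[s$parent %in% tree$root & s$kind == "dendrite"]
  # oracle: exhaustive walk of per-stem path intervals
  start <- motorunit:::section_path_start(tree)
  stem_of <- function(id) {
    chain <- motorunit:::section_chain(tree, id)
    chain[1]
  }
  dend <- s[s$kind == "dendrite", ]
  intervals <- tibble::tibble(
    stem = vapply(dend$id, stem_of, numeric(1)),
    lo = start[match(dend$id, s$id)] / 1000,
    hi = (start[match(dend$id, s$id)] + dend$length) / 1000
  )
  for (d in seq(0.1, 1, by = 0.1)) {
    sites <- select_band(tree, d)
    expect_gt(nrow(sites), 0)
    covered <- vapply(stems, function(st) {
      any(intervals$stem == st & intervals$lo <= d + 0.1 &
            intervals$hi >= d - 0.1)
    }, logical(1))
    expect_true(all(covered), label = paste("band", d, "on every stem"))
  }
})

test_that("select_band selects midpoints in range on all branches", {
  tree <- single_cable_tree(1500, 4)
  sites <- select_band(tree, 0.6, 0.1, uniform_passive())
  expect_true(all(sites$path_mm >= 0.5 & sites$path_mm <= 0.7))
  expect_error(select_band(tree, 5, 0.1), "empty band")

  two <- neurite_tree(tibble::tibble(
    id = 1:3, parent = c(NA, 1L, 1L),
    kind = c("soma", "dendrite", "dendrite"),
    length = c(40, 1500, 1500), diam_prox = c(40, 4, 4),
    diam_dist = c(40, 4, 4)
  ))
  s1 <- select_band(single_cable_tree(1500, 4, 40), 0.6, 0.1)
  s2 <- select_band(two, 0.6, 0.1)
  expect_equal(nrow(s2), 2 * nrow(s1))
})

test_that("electrotonic path length matches the definition", {
  # uniform cable d = 4 um, R_m = 10 kOhm cm^2, R_i = 100 Ohm cm:
  # lambda = sqrt(10000 * 4e-4 / 400) cm = 1 mm
  tree <- single_cable_tree(2000, 4)
  pp <- uniform_passive(rm = 10, ri = 100)
  lam_mm <- sqrt(10000 * 4e-4 / (4 * 100)) * 10
  dend <- tree$sections$id[tree$sections$kind == "dendrite"]
  expect_equal(electrotonic_path(tree, dend, arc = lam_mm * 1000 / 2000, pp),
               1, tolerance = 1e-3)
  # zero-length path at the soma end
  expect_equal(electrotonic_path(tree, dend, arc = 0, pp), 0)

  # tapering cable: compare against fine-grid quadrature of 1/lambda(x)
  taper <- neurite_tree(tibble::tibble(
    id = 1:2, parent = c(NA, 1L), kind = c("soma", "dendrite"),
    length = c(40, 1000), diam_prox = c(40, 6), diam_dist = c(40, 2)
  ))
  got <- electrotonic_path(taper, 2, arc = 1, pp)
  oracle <- stats::integrate(function(x_um) {
    d <- 6 + (2 - 6) * x_um / 1000
    lam_um <- sqrt(10000 * d * 1e-4 / 400) * 1e4
    1 / lam_um
  }, 0, 1000, rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("electrotonic distance grows monotonically with path length", {
  tree <- synthetic_motoneuron(n_stems = 2, seed = 5)
  pp <- passive_params()
  dend <- tree$sections[tree$sections$kind == "dendrite", ]
  chain_id <- dend$id[1]
  arcs <- seq(0.1, 1, by = 0.3)
  vals <- vapply(arcs, function(a) electrotonic_path(tree, chain_id, a, pp),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})
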