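test_that("superposition of identical point sets is the identity", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  k <- kabsch(P, P)
  expect_equal(k$rmsd, 0, tolerance = 1e-12)
  expect_equal(k$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(k$transform$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("an exact rigid motion is recovered to machine precision", {
  set.seed(2)
  Q <- matrix(rnorm(30), ncol = 3)
  R <- augminr:::rotation_matrix(c(0, 0, 1), 30)
  P <- sweep(Q %*% t(R), 2, c(1, 2, 3), "+")
  k <- kabsch(P, Q)
  expect_lt(k$rmsd, 1e-9)
  moved <- apply_transform(P, k$transform)
  expect_lt(max(abs(moved - Q)), 1e-9)
})

test_that("least-squares fit beats a 10,000-rotation random search", {
  set.seed(3)
  Q <- matrix(rnorm(30), ncol = 3)
  R <- augminr:::rotation_matrix(c(1, 1, 0), 40)
  P <- Q %*% t(R) + matrix(rnorm(30, sd = 0.5), ncol = 3)
  k <- kabsch(P, Q)
  expect_lte(k$rmsd, random_rotation_rmsd(P, Q, n = 10000) + 1e-12)
  # and never worse than leaving the points untransformed
  expect_lte(k$rmsd, rmsd(P, Q))
})

test_that("superposition matches a quaternion-grid search on 5-point sets", {
  for (seed in 1:3) {
    set.seed(seed)
    Q <- matrix(rnorm(15), ncol = 3)
    P <- Q %*% t(augminr:::rotation_matrix(rnorm(3), 25 * seed)) +
      matrix(rnorm(15, sd = 0.3), ncol = 3)
    k <- kabsch(P, Q)
    grid_best <- quaternion_grid_rmsd(P, Q, n = 14)
    expect_lte(k$rmsd, grid_best + 1e-12)
    # the grid comes within its resolution of the optimum
    expect_lt(grid_best - k$rmsd, 0.5)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  P <- matrix(rnorm(12), ncol = 3)
  P[1, 1] <- NA
  expect_error(kabsch(P, matrix(rnorm(12), ncol = 3)), "non-finite")
})

test_that("aligning identical ensemble members gives zero rmsd", {
  b <- make_bundle(2, 30)
  al <- align_ensemble(list(b, b, b))
  expect_equal(al$rmsd$rmsd, c(0, 0, 0), tolerance = 1e-9)
})

test_that("aligning a hinge ensemble on the fixed half isolates the motion", {
  h <- make_hinge_ensemble(30, axis = c(0, 1, 0), split_residue = 40,
                           n_chains = 2, n_res = 80)
  coreA <- bundle_selection(2, 1, 40)
  al <- align_ensemble(h$ensemble, core = coreA)
  expect_lt(al$rmsd$rmsd[2], 1e-9)          # fixed half superposes exactly
  segB <- lapply(al$ensemble, function(s) coords(s[s$resno > 40, ]))
  expect_gt(rmsd(segB[[1]], segB[[2]]), 1)  # mobile half clearly moved
})

test_that("inconsistent residue content across members is an error", {
  b <- make_bundle(2, 30)
  b2 <- atom_tbl(b[b$resno != 10, ])
  expect_error(align_ensemble(list(b, b2), core = bundle_selection(2, 1, 30)),
               "offending")
})

test_that("core rmsd after alignment is bounded by the planted noise", {
  flex <- make_flex_ensemble(profile = rep(0.5, 40), n_models = 25,
                             seed = 5, n_chains = 2)
  al <- align_ensemble(flex$ensemble, core = bundle_selection(2, 1, 40))
  expect_true(all(al$rmsd$rmsd <= 0.5 * 3))
})

test_that("extreme pair is exhaustive and deterministic", {
  b <- make_bundle(2, 30)
  expect_equal(extreme_pair(list(b, b))[c("i", "j")], list(i = 1L, j = 2L))
  # model 5 rotated at a hinge, others identical: pair must contain 5
  h <- make_hinge_ensemble(25, split_residue = 15, n_chains = 2, n_res = 30)
  ens5 <- c(rep(list(h$ensemble[[1]]), 4), h$ensemble[2])
  ep <- extreme_pair(ens5)
  expect_true(5 %in% c(ep$i, ep$j))
  # equals brute force over all pairs on a 10-model ensemble
  flex <- make_flex_ensemble(profile = runif(30, 0, 2), n_models = 10,
                             seed = 9, n_chains = 2)
  ep2 <- extreme_pair(flex$ensemble)
  sc <- augminr:::shared_ca(flex$ensemble)
  brute <- -1; bi <- bj <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    r <- rmsd(sc$xyz[[i]], sc$xyz[[j]])
    if (r > brute) { brute <- r; bi <- i; bj <- j }
  }
  expect_equal(c(ep2$i, ep2$j), c(bi, bj))
  expect_equal(ep2$rmsd, brute)
})

test_that("flexibility profile is zero for identical copies", {
  b <- make_bundle(2, 25)
  for (mode in c("extreme_pair", "ensemble_rmsd")) {
    pr <- flexibility_profile(list(b, b, b), mode = mode)
    expect_true(all(pr$deviation == 0))
  }
  expect_error(flexibility_profile(list(b)), "at least 2")
})

test_that("an exactly displaced residue shows its displacement", {
  b <- make_bundle(1, 20)
  b2 <- b
  b2$x[10] <- b2$x[10] + 10
  pr <- flexibility_profile(list(b, atom_tbl(b2)), mode = "extreme_pair")
  expect_equal(pr$deviation[pr$resno == 10], 10)
  expect_equal(sum(pr$deviation > 0), 1)
})

test_that("a planted sinusoidal amplitude profile is recovered", {
  prof <- 1.5 + sin(seq(0, 3 * pi, length.out = 60))
  flex <- make_flex_ensemble(profile = prof, n_models = 25, seed = 4,
                             n_chains = 2)
  al <- align_ensemble(flex$ensemble, core = bundle_selection(2, 1, 60))
  pr <- flexibility_profile(al$ensemble, mode = "ensemble_rmsd")
  per_res <- tapply(pr$deviation, pr$resno, mean)
  expect_gte(cor(as.numeric(per_res), prof), 0.9)
})

test_that("ensemble-rmsd profile is invariant to a global rigid motion", {
  flex <- make_flex_ensemble(profile = runif(30, 0, 2), n_models = 8,
                             seed = 6, n_chains = 2)
  pr1 <- flexibility_profile(flex$ensemble, mode = "ensemble_rmsd")
  tf <- rigid_transform(augminr:::rotation_matrix(c(1, 2, 3), 77),
                        c(5, -4, 12))
  moved <- lapply(flex$ensemble, apply_transform, tf = tf)
  pr2 <- flexibility_profile(moved, mode = "ensemble_rmsd")
  expect_equal(pr2$deviation, pr1$deviation, tolerance = 1e-9)
})

test_that("hinge rotation is measured exactly on synthetic two-state pairs", {
  h <- make_hinge_ensemble(23, axis = c(0, 0, 1), split_residue = 50)
  ref <- bundle_selection(4, 1, 50)
  mob <- bundle_selection(4, 51, 100)
  hm <- rotation_between(h$ensemble[[1]], h$ensemble[[2]], ref, mob)
  expect_equal(hm$angle_deg, 23, tolerance = 1e-6)
  expect_gte(abs(sum(hm$axis * h$truth$axis)), 1 - 1e-6)
  expect_lt(hm$rmsd_mobile, 1e-9)
  # identical structures: zero angle
  hm0 <- rotation_between(h$ensemble[[1]], h$ensemble[[1]], ref, mob)
  expect_equal(hm0$angle_deg, 0, tolerance = 1e-9)
})

test_that("hinge angle is symmetric in the structure order", {
  h <- make_hinge_ensemble(37, axis = c(1, 1, 1), split_residue = 30,
                           n_chains = 2, n_res = 60)
  ref <- bundle_selection(2, 1, 30)
  mob <- bundle_selection(2, 31, 60)
  ab <- rotation_between(h$ensemble[[1]], h$ensemble[[2]], ref, mob)
  ba <- rotation_between(h$ensemble[[2]], h$ensemble[[1]], ref, mob)
  expect_equal(ab$angle_deg, ba$angle_deg, tolerance = 1e-9)
  # recovered rotation composed with the truth is the identity
  R_rec <- augminr:::rotation_matrix(ab$axis, ab$angle_deg)
  R_true <- augminr:::rotation_matrix(h$truth$axis, h$truth$angle_deg)
  expect_lt(max(abs(R_rec %*% t(R_true) - diag(3))), 1e-6)
})

test_that("the 180-degree boundary is handled", {
  h <- make_hinge_ensemble(180, axis = c(0, 1, 0), split_residue = 30,
                           n_chains = 2, n_res = 60)
  hm <- rotation_between(h$ensemble[[1]], h$ensemble[[2]],
                         bundle_selection(2, 1, 30),
                         bundle_selection(2, 31, 60))
  expect_equal(hm$angle_deg, 180, tolerance = 1e-6)
})

test_that("centroid-mode rotation works without a reference selection", {
  b <- make_bundle(1, 40)
  R <- augminr:::rotation_matrix(c(0, 0, 1), 170)
  b2 <- set_coords(b, sweep(coords(b) %*% t(R), 2, c(100, 0, 0), "+"))
  hm <- rotation_between(b, atom_tbl(b2), selection(),
                         selection(S1 = c(1, 40)),
                         center_mode = "centroid")
  expect_equal(hm$angle_deg, 170, tolerance = 1e-6)
})

test_that("an identity splice recipe reproduces the model", {
  b <- make_bundle(2, 40)
  recipe <- list(splices = tibble::tibble(
    model_id = "m", subunit = c("S1", "S2"), start = 1L, end = 40L))
  out <- splice_composite(recipe, list(m = b))
  expect_equal(nrow(out), nrow(b))
  expect_equal(coords(out), coords(atom_tbl(
    dplyr::arrange(b, chain, resno, icode, elety))))
})

test_that("the tetramer-joining recipe conserves the recipe arithmetic", {
  mk <- function(subunit, from, to) {
    p <- make_bundle(1, to - from + 1)
    p$chain <- subunit
    p$resno <- p$resno + from - 1L
    p
  }
  tiii <- atom_tbl(dplyr::bind_rows(mk("HAUS3", 96, 434),
                                    mk("HAUS5", 80, 489) |>
                                      dplyr::mutate(x = x + 40)))
  arm <- atom_tbl(dplyr::bind_rows(mk("HAUS3", 96, 434),
                                   mk("HAUS5", 80, 489) |>
                                     dplyr::mutate(x = x + 40)))
  recipe <- augmin_splice_recipe()
  out <- splice_composite(recipe, list(tiii = tiii, arm_tii = arm))
  n_expected <- sum(recipe$splices$end - recipe$splices$start + 1)
  expect_equal(nrow(out), n_expected)
  expect_equal(anyDuplicated(paste(out$chain, out$resno)), 0)
})

test_that("overlapping splices are rejected naming residues", {
  b <- make_bundle(1, 30)
  recipe <- list(splices = tibble::tibble(
    model_id = c("m", "m"), subunit = "S1",
    start = c(1L, 20L), end = c(25L, 30L)))
  expect_error(splice_composite(recipe, list(m = b)), "S1:20")
})

test_that("deletions remove exactly the stated residues and warn when vacuous", {
  b <- make_bundle(1, 30)
  recipe <- list(
    splices = tibble::tibble(model_id = "m", subunit = "S1",
                             start = 1L, end = 30L),
    deletions = selection(S1 = c(10, 12)))
  out <- splice_composite(recipe, list(m = b))
  expect_equal(nrow(out), 27)
  expect_false(any(out$resno %in% 10:12))
  recipe$deletions <- selection(S1 = c(200, 210))
  expect_warning(splice_composite(recipe, list(m = b)), "matches no")
})

test_that("splice placements transform their source rigidly", {
  b <- make_bundle(1, 20)
  tf <- rigid_transform(augminr:::rotation_matrix(c(0, 0, 1), 90),
                        c(10, 0, 0))
  recipe <- list(splices = tibble::tibble(
    model_id = "m", subunit = "S1", start = 1L, end = 20L))
  out <- splice_composite(recipe, list(m = b), placements = list(m = tf))
  expect_equal(unname(coords(out)),
               unname(apply_transform(coords(atom_tbl(b)), tf)),
               tolerance = 1e-12)
})
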