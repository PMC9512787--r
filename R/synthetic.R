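#' Synthetic helix-bundle model
#'
#' Builds an ideal Calpha-trace helix bundle: each chain is an ideal
#' alpha-helix (rise and twist per residue as given) running along z,
#' with chain axes arranged on a circle so neighbouring chains sit
#' `spacing` Angstrom apart. Chains are named subunit-style (`S1`,
#' `S2`, ...). A deterministic stand-in for the extensive coiled-coil
#' segments of HAUS-like subunits — not a physical coiled-coil builder
#' (no supercoiling, no side chains).
#'
#' @param n_chains number of chains (>= 1)
#' @param n_res residues per chain
#' @param rise helical rise per residue in Angstrom (default 1.5)
#' @param twist helical twist per residue in degrees (default 100)
#' @param helix_radius Calpha helix radius (default 2.3)
#' @param spacing distance between neighbouring chain axes (default 12)
#' @return an [atom_tbl()] of Calpha atoms
#' @export
make_bundle <- function(n_chains = 4, n_res = 100, rise = 1.5,
                        twist = 100, helix_radius = 2.3, spacing = 12) {
  if (n_chains < 1 || n_res < 1 || rise <= 0 || helix_radius <= 0) {
    stop("bundle dimensions must be positive", call. = FALSE)
  }
  bundle_radius <- if (n_chains == 1) 0 else spacing / (2 * sin(pi / n_chains))
  rows <- purrr::map_dfr(seq_len(n_chains), function(k) {
    phi <- 2 * pi * (k - 1) / n_chains
    cx <- bundle_radius * cos(phi)
    cy <- bundle_radius * sin(phi)
    i <- seq_len(n_res)
    th <- (i - 1) * twist * pi / 180
    tibble::tibble(
      model = 1L, chain = paste0("S", k), resno = as.integer(i),
      icode = "", resid = "ALA", elety = "CA", elesy = "C",
      x = cx + helix_radius * cos(th),
      y = cy + helix_radius * sin(th),
      z = (i - 1) * rise
    )
  })
  atom_tbl(rows)
}

#' Synthetic two-state hinge ensemble with known rotation
#'
#' Returns two conformations of a helix bundle related by a known rigid
#' rotation of everything past a split residue — an idealised two-state
#' clamp like the TII N-clamp/C-clamp motion, with the ground truth
#' recorded so hinge-measurement code can be checked exactly.
#'
#' Model 2 equals model 1 with all residues `resno > split_residue`
#' (every chain) rotated by `angle_deg` about `axis` through the
#' centroid of the split-residue Calpha atoms.
#'
#' @param angle_deg hinge angle in degrees
#' @param axis rotation axis (any non-zero 3-vector)
#' @param split_residue residue number separating fixed from mobile part
#'   (interior: `1 < split_residue < n_res`)
#' @inheritParams make_bundle
#' @return a list: `ensemble` (two atom tables), `truth` (list
#'   `angle_deg`, `axis` unit vector, `split_residue`, `pivot`)
#' @export
make_hinge_ensemble <- function(angle_deg, axis = c(1, 0, 0),
                                split_residue = 50, n_chains = 4,
                                n_res = 100, ...) {
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis must be non-zero", call. = FALSE)
  if (split_residue <= 1 || split_residue >= n_res) {
    stop("split_residue must be interior to the chain", call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  base <- make_bundle(n_chains = n_chains, n_res = n_res, ...)
  pivot <- colMeans(coords(base[base$resno == split_residue, ]))
  R <- rotation_matrix(axis, angle_deg)
  moved <- base
  mob <- moved$resno > split_residue
  xyz <- coords(moved)
  xyz[mob, ] <- sweep(sweep(xyz[mob, , drop = FALSE], 2, pivot) %*% t(R),
                      2, pivot, "+")
  moved <- set_coords(moved, xyz)
  list(ensemble = list(base, moved),
       truth = list(angle_deg = angle_deg, axis = axis,
                    split_residue = split_residue, pivot = pivot))
}

#' Synthetic flexible ensemble with planted amplitude profile
#'
#' Generates an ensemble of copies of a helix bundle in which each
#' Calpha is displaced along an isotropic random direction by a
#' `N(0, sigma_r)` magnitude, with per-residue `sigma_r` taken from a
#' planted amplitude profile — a rigid core with flexible segments, the
#' statistical structure that per-residue ensemble-RMSD profiling is
#' meant to recover (recovered RMSD ~ `sigma_r`).
#'
#' @param profile numeric vector of per-residue sigma (Angstrom), length
#'   `n_res`, applied to every chain
#' @param n_models ensemble size (>= 2)
#' @param seed RNG seed (R Mersenne-Twister; fixed seed gives identical
#'   output on all platforms)
#' @inheritParams make_bundle
#' @return a list: `ensemble` (list of atom tables), `truth` (tibble
#'   `resno`, `sigma`)
#' @export
make_flex_ensemble <- function(profile, n_models = 25, seed = 1,
                               n_chains = 4, n_res = length(profile), ...) {
  if (n_models < 2) stop("need n_models >= 2", call. = FALSE)
  if (length(profile) != n_res || any(profile < 0)) {
    stop("profile must be length n_res and non-negative", call. = FALSE)
  }
  base <- make_bundle(n_chains = n_chains, n_res = n_res, ...)
  sig <- profile[base$resno]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ensemble <- purrr::map(seq_len(n_models), function(m) {
    n <- nrow(base)
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    mag <- rnorm(n, 0, sig)
    set_coords(base, coords(base) + dir * mag)
  })
  list(ensemble = ensemble,
       truth = tibble::tibble(resno = seq_len(n_res), sigma = profile))
}

#' Synthetic crosslink table with planted ground truth
#'
#' Samples residue pairs from a structure so that a chosen number have
#' Calpha-Calpha distance within the threshold (planted satisfied) and a
#' chosen number beyond it (planted violated); draws aggregate scores
#' from a log-normal straddling the conventional 250 filter threshold;
#' optionally injects duplicate rows with strictly lower scores (the
#' replicate-duplication that deduplication must undo). Residue types
#' are labelled K on one end and one of K/S/T/Y on the other, emulating
#' BS3 chemistry in the table only (coordinates are untouched).
#'
#' @param s atom table (Calpha-bearing)
#' @param n_satisfied,n_violated planted counts
#' @param d_max distance threshold in Angstrom (default 30)
#' @param score_meanlog,score_sdlog log-normal score parameters
#'   (defaults `log(250)`, 0.5 — scores straddle 250)
#' @param n_duplicates duplicate rows to inject
#' @param seed RNG seed
#' @return a list: `table` (crosslink tibble, originals then
#'   duplicates), `truth` (tibble with planted `distance` and `label`
#'   per unique pair)
#' @export
make_crosslinks <- function(s, n_satisfied = 90, n_violated = 10,
                            d_max = 30, score_meanlog = log(250),
                            score_sdlog = 0.5, n_duplicates = 0,
                            seed = 1) {
  ca <- ca_atoms(s)
  xyz <- coords(ca)
  n <- nrow(ca)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dists <- dm[pairs]
  sat_pool <- which(dists <= d_max & dists > 1e-6)
  vio_pool <- which(dists > d_max)
  if (length(sat_pool) < n_satisfied || length(vio_pool) < n_violated) {
    stop("structure supports at most ", length(sat_pool),
         " satisfied and ", length(vio_pool), " violated pairs",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  take <- c(sample(sat_pool, n_satisfied), sample(vio_pool, n_violated))
  label <- rep(c("satisfied", "violated"), c(n_satisfied, n_violated))
  i1 <- pairs[take, 1]; i2 <- pairs[take, 2]
  tbl <- tibble::tibble(
    protein1 = ca$chain[i1], res1 = ca$resno[i1], type1 = "K",
    protein2 = ca$chain[i2], res2 = ca$resno[i2],
    type2 = sample(c("K", "S", "T", "Y"), length(take), replace = TRUE),
    score = rlnorm(length(take), score_meanlog, score_sdlog),
    n_spectra = sample(1:5, length(take), replace = TRUE)
  )
  truth <- tibble::tibble(
    key = xl_pair_key(tbl$protein1, tbl$res1, tbl$protein2, tbl$res2),
    distance = dists[take], label = label)
  if (n_duplicates > 0) {
    idx <- sample(nrow(tbl), n_duplicates, replace = n_duplicates > nrow(tbl))
    dup <- tbl[idx, ]
    dup$score <- dup$score * runif(n_duplicates, 0.5, 0.9)
    tbl <- dplyr::bind_rows(tbl, dup)
  }
  list(table = tbl, truth = truth)
}
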