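#' Align a model ensemble on a core selection
#'
#' Superposes every member of an ensemble of predicted models onto a
#' reference member using least-squares superposition over the Calpha
#' atoms of a core selection — the way ensembles of structure predictions
#' are compared (e.g. a tetramer ensemble superposed on its full length,
#' or a clamp-like complex superposed on one clamp half only so the hinge
#' motion of the other half becomes visible).
#'
#' Every member must resolve the core to the same residue set; residues
#' missing from *all* members are dropped with a report, but a residue
#' present in some members and absent in others is an error naming the
#' offending models.
#'
#' @param ensemble list of atom tables sharing chain naming
#' @param core a [selection()]; default: all residues of the reference
#' @param map a [chain_map()]; default identity
#' @param reference index of the fixed reference member (default 1, by
#'   convention the highest-confidence model first)
#' @return a list: `ensemble` (aligned atom tables), `rmsd` (tibble
#'   `model`, `rmsd` of the core fit), `core_residues` (tibble of the
#'   residues used)
#' @export
align_ensemble <- function(ensemble, core = NULL,
                           map = identity_chain_map(ensemble[[1]]),
                           reference = 1) {
  if (length(ensemble) < 1) stop("empty ensemble", call. = FALSE)
  if (is.null(core)) {
    ca <- ca_atoms(ensemble[[reference]])
    rng <- dplyr::summarise(dplyr::group_by(ca, .data$chain),
                            start = min(.data$resno), end = max(.data$resno))
    core <- tibble::tibble(subunit = rng$chain, start = rng$start,
                           end = rng$end)
  }
  keys <- purrr::map(ensemble, function(s) {
    res <- resolve_selection(s, core, map, atoms = "CA")
    paste(res$atoms$chain, res$atoms$resno, res$atoms$icode)
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) < 3) {
    stop("fewer than 3 shared core residues across the ensemble",
         call. = FALSE)
  }
  bad <- which(purrr::map_int(keys, length) != length(shared))
  if (length(bad) > 0) {
    stop("inconsistent core residue content across ensemble members; ",
         "offending model(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  core_xyz <- function(s) {
    res <- resolve_selection(s, core, map, atoms = "CA")$atoms
    k <- paste(res$chain, res$resno, res$icode)
    coords(res[match(shared, k), ])
  }
  ref_xyz <- core_xyz(ensemble[[reference]])
  fits <- purrr::imap(ensemble, function(s, i) {
    if (i == reference) {
      return(list(s = s, rmsd = 0))
    }
    k <- kabsch(core_xyz(s), ref_xyz)
    list(s = apply_transform(s, k$transform), rmsd = k$rmsd)
  })
  parts <- strsplit(shared, " ", fixed = TRUE)
  list(
    ensemble = purrr::map(fits, "s"),
    rmsd = tibble::tibble(model = seq_along(ensemble),
                          rmsd = purrr::map_dbl(fits, "rmsd")),
    core_residues = tibble::tibble(
      chain = purrr::map_chr(parts, 1),
      resno = as.integer(purrr::map_chr(parts, 2)))
  )
}

# Calpha coordinates of the residues shared by all members, as a list of
# matrices with identical row order; helper for profile/extreme-pair
shared_ca <- function(ensemble) {
  keys <- purrr::map(ensemble, function(s) {
    ca <- ca_atoms(s)
    paste(ca$chain, ca$resno, ca$icode)
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) stop("no shared Calpha residues", call. = FALSE)
  xyz <- purrr::map(ensemble, function(s) {
    ca <- ca_atoms(s)
    k <- paste(ca$chain, ca$resno, ca$icode)
    coords(ca[match(shared, k), ])
  })
  parts <- strsplit(shared, " ", fixed = TRUE)
  list(xyz = xyz,
       residues = tibble::tibble(chain = purrr::map_chr(parts, 1),
                                 resno = as.integer(purrr::map_chr(parts, 2))))
}

#' The two most distinct conformations of an aligned ensemble
#'
#' Exhaustively compares all member pairs by global Calpha RMSD (on the
#' residues shared by all members) and returns the pair with the largest
#' deviation — the "two most extreme conformations" of an ensemble. Ties
#' break deterministically to the lexicographically first `(i, j)`.
#'
#' @param ensemble list of aligned atom tables (>= 2)
#' @return a list: `i`, `j` (member indices, `i < j`), `rmsd`
#' @export
extreme_pair <- function(ensemble) {
  n <- length(ensemble)
  if (n < 2) stop("need at least 2 models", call. = FALSE)
  sc <- shared_ca(ensemble)
  best <- list(i = 1L, j = 2L, rmsd = -1)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      r <- rmsd(sc$xyz[[i]], sc$xyz[[j]])
      if (r > best$rmsd + 1e-12) best <- list(i = i, j = j, rmsd = r)
    }
  }
  best
}

#' Per-residue flexibility profile of an aligned ensemble
#'
#' Quantifies where an ensemble of superposed models disagrees, residue
#' by residue. Two modes:
#'
#' * `"extreme_pair"` — per-residue Calpha deviation between the two most
#'   distinct members (see [extreme_pair()]); the convention behind
#'   "coloured by RMSD between the two most extreme conformations" figures,
#'   typically displayed on a 0-10 Angstrom scale.
#' * `"ensemble_rmsd"` — per-residue root-mean-square Calpha deviation from
#'   the per-residue ensemble mean, over all members.
#'
#' Only residues shared by all members are profiled.
#'
#' @param ensemble list of aligned atom tables (>= 2); align first with
#'   [align_ensemble()]
#' @param mode `"extreme_pair"` or `"ensemble_rmsd"`
#' @return a tibble of class `flex_profile`: `chain`, `resno`,
#'   `deviation` (Angstrom), with the mode and extreme pair (if any) as
#'   attributes
#' @export
flexibility_profile <- function(ensemble,
                                mode = c("extreme_pair", "ensemble_rmsd")) {
  mode <- match.arg(mode)
  if (length(ensemble) < 2) stop("need at least 2 models", call. = FALSE)
  sc <- shared_ca(ensemble)
  if (mode == "extreme_pair") {
    ep <- extreme_pair(ensemble)
    d <- sqrt(rowSums((sc$xyz[[ep$i]] - sc$xyz[[ep$j]])^2))
  } else {
    arr <- simplify2array(sc$xyz)            # nres x 3 x nmodel
    mean_xyz <- apply(arr, c(1, 2), mean)
    d <- sqrt(apply((arr - as.vector(mean_xyz))^2, 1, sum) /
                length(ensemble))
    ep <- NULL
  }
  out <- dplyr::bind_cols(sc$residues, tibble::tibble(deviation = d))
  class(out) <- c("flex_profile", class(out))
  attr(out, "mode") <- mode
  attr(out, "extreme_pair") <- ep
  out
}
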