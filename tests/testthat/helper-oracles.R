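# Independent oracles and small fixture builders used across the suite.

# Selection covering residues `from`..`to` on every chain S1..Sn
bundle_selection <- function(n_chains, from, to) {
  args <- stats::setNames(
    rep(list(c(from, to)), n_chains),
    paste0("S", seq_len(n_chains)))
  do.call(augminr::selection, args)
}

# --- brute-force global alignment with affine gaps ---------------------
# Enumerates every alignment path (match/insert/delete) of two short
# sequences and scores it with BLOSUM62 + affine gaps; returns the
# optimal score and the identity (terminal-gap columns excluded) of one
# optimal alignment. Exponential: keep sequences short (<= 6).
brute_force_align <- function(a, b, gap_open = 10, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, pa = NULL, pb = NULL)
  rec <- function(i, j, pa, pb, score, prev) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score) best <<- list(score = score, pa = pa, pb = pb)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, c(pa, A[i]), c(pb, B[j]),
          score + sub[A[i], B[j]], "M")
    }
    if (i <= length(A)) {
      pen <- if (identical(prev, "D")) gap_extend else gap_open + gap_extend
      rec(i + 1, j, c(pa, A[i]), c(pb, "-"), score - pen, "D")
    }
    if (j <= length(B)) {
      pen <- if (identical(prev, "I")) gap_extend else gap_open + gap_extend
      rec(i, j + 1, c(pa, "-"), c(pb, B[j]), score - pen, "I")
    }
  }
  rec(1L, 1L, character(0), character(0), 0, "S")
  id <- augminr:::ident_from_alignment(best$pa, best$pb)
  list(score = best$score, identity = id$identity)
}

# --- random-rotation search oracle for superposition -------------------
# RMSD of the best of `n` random rotations (translations optimal, i.e.
# centroids aligned); a correct least-squares superposition must never
# be beaten by it.
random_rotation_rmsd <- function(mobile, reference, n = 10000, seed = 42) {
  set.seed(seed)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (k in seq_len(n)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    r <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
    if (r < best) best <- r
  }
  best
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# deterministic quaternion grid (n^4 sign-reduced) for the grid-search
# superposition oracle
quaternion_grid_rmsd <- function(mobile, reference, n = 14) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  g <- seq(-1, 1, length.out = n)
  best <- Inf
  for (w in g) for (x in g) for (y in g) for (z in g) {
    nrm <- sqrt(w^2 + x^2 + y^2 + z^2)
    if (nrm < 1e-8) next
    R <- quat_to_rot(c(w, x, y, z) / nrm)
    r <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
    if (r < best) best <- r
  }
  best
}

# small hand-written PDB text fixture (single chain, Calpha only)
write_ca_pdb <- function(path, resno, xyz, chain = "A", icode = NULL) {
  icode <- icode %||% rep("", length(resno))
  lines <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, resno[i], ifelse(icode[i] == "", " ", icode[i]),
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# directory where deposited reference inputs (PDB/EMDB accessions and
# exported crosslink tables) are expected for the reproduction tests
reference_dir <- function() {
  getOption("augminr.reference_dir",
            file.path(path.expand("~"), "augmin-reference"))
}

reference_file <- function(...) file.path(reference_dir(), c(...))
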