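#' Read a crosslink residue-pair table
#'
#' Reads the residue-pair table exported from crosslinking-MS search
#' software (one row per identified crosslink site, possibly with
#' duplicate entries for the same residue pair from different replicates).
#' Mandatory columns (renameable via `cols`): `protein1`, `res1`,
#' `protein2`, `res2`, `score` (the aggregate score, a sum of
#' -ln(expectation) spectrum scores). Any further columns are carried
#' along.
#'
#' @param path TSV or CSV file (dialect from extension, or set `delim`)
#' @param cols named character vector mapping standard names to file
#'   column names, e.g. `c(score = "AggregateScore")`
#' @param delim field delimiter override
#' @return a tibble with at least the five standard columns
#' @export
read_crosslinks <- function(path, cols = character(), delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  std <- c("protein1", "res1", "protein2", "res2", "score")
  name_of <- function(nm) if (nm %in% names(cols)) cols[[nm]] else nm
  for (nm in std) {
    fn <- name_of(nm)
    if (!fn %in% names(raw)) {
      stop("crosslink table lacks mandatory column '", fn, "'",
           call. = FALSE)
    }
  }
  out <- raw
  for (nm in std) names(out)[names(out) == name_of(nm)] <- nm
  for (nm in c("res1", "res2", "score")) {
    v <- suppressWarnings(as.numeric(out[[nm]]))
    bad <- which(is.na(v) & !is.na(out[[nm]]))
    if (length(bad) > 0) {
      stop("non-numeric ", nm, " in crosslink table row ", bad[1],
           call. = FALSE)
    }
    out[[nm]] <- v
  }
  out$res1 <- as.integer(out$res1)
  out$res2 <- as.integer(out$res2)
  if (any(out$res1 < 1 | out$res2 < 1, na.rm = TRUE)) {
    stop("residue numbers must be >= 1", call. = FALSE)
  }
  if (any(out$score < 0, na.rm = TRUE)) {
    stop("aggregate scores must be non-negative", call. = FALSE)
  }
  out
}

# canonical unordered pair key of a crosslink row
xl_pair_key <- function(protein1, res1, protein2, res2) {
  a <- paste0(protein1, ":", res1)
  b <- paste0(protein2, ":", res2)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Deduplicate and score-filter a crosslink table
#'
#' Collapses duplicate observations of the same (unordered) residue pair
#' to the copy with the highest aggregate score (ties keep the first row
#' in input order), then applies a strict score filter (`score >
#' score_min`; a link scoring exactly `score_min` is excluded). The
#' result is sorted by descending score. With the defaults this is the
#' "keep the best copy, then aggregate score higher than 250" selection
#' used to pick high-confidence crosslinks for model validation.
#'
#' @param xl crosslink tibble (see [read_crosslinks()])
#' @param score_min strict lower score bound (default 250)
#' @return filtered tibble, one row per unique residue pair
#' @export
dedup_and_filter <- function(xl, score_min = 250) {
  if (nrow(xl) == 0) return(xl)
  xl$.key <- xl_pair_key(xl$protein1, xl$res1, xl$protein2, xl$res2)
  xl$.row <- seq_len(nrow(xl))
  # keep the max-score copy per pair; ties keep earliest input row
  out <- xl |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.row) |>
    dplyr::distinct(.data$.key, .keep_all = TRUE) |>
    dplyr::filter(.data$score > score_min) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.row)
  out$.key <- NULL
  out$.row <- NULL
  out
}

#' Map crosslinks onto an atomic model
#'
#' Resolves both endpoints of each crosslink to Calpha coordinates of a
#' model (via a subunit-to-chain map) and computes the Euclidean
#' Calpha-Calpha distance. When a subunit maps to several chains the
#' minimum distance over all chain combinations is taken. Links with an
#' endpoint absent from the model are kept, flagged `unmapped`, with
#' `NA` distance. `type` is `"intra"` when both endpoints are on the same
#' subunit.
#'
#' @param xl crosslink tibble
#' @param s atom table (single conformation)
#' @param map [chain_map()] covering every protein in `xl`
#' @return `xl` with columns `distance`, `mapped` (logical), `type`
#' @export
map_crosslinks <- function(xl, s, map = identity_chain_map(s)) {
  unknown <- setdiff(unique(c(xl$protein1, xl$protein2)), map$subunit)
  if (length(unknown) > 0) {
    stop("crosslink protein(s) not in chain map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ca <- ca_atoms(dplyr::filter(s, .data$model == min(.data$model)))
  ca_key <- paste(ca$chain, ca$resno)
  ca_xyz <- coords(ca)
  endpoint_xyz <- function(protein, resno) {
    chains <- map_chains(map, protein)
    idx <- match(paste(chains, resno), ca_key)
    idx[!is.na(idx)]
  }
  n <- nrow(xl)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    i1 <- endpoint_xyz(xl$protein1[i], xl$res1[i])
    i2 <- endpoint_xyz(xl$protein2[i], xl$res2[i])
    if (length(i1) == 0 || length(i2) == 0) next
    d <- sqrt(outer(rowSums(ca_xyz[i1, , drop = FALSE]^2),
                    rowSums(ca_xyz[i2, , drop = FALSE]^2), "+") -
                2 * ca_xyz[i1, , drop = FALSE] %*% t(ca_xyz[i2, , drop = FALSE]))
    distance[i] <- min(d)
  }
  xl$distance <- distance
  xl$mapped <- !is.na(distance)
  xl$type <- ifelse(xl$protein1 == xl$protein2, "intra", "inter")
  xl
}

#' Validate mapped crosslinks against a distance threshold
#'
#' Classifies each mapped crosslink as satisfied (Calpha-Calpha distance
#' `<= d_max`, inclusive) or violated, and summarises: counts, the
#' percent satisfied among mapped links (rounded to integer for
#' reporting, as conventional), a symmetric per-subunit-pair count
#' matrix, and an export table with scores divided by
#' `score_norm_factor` for downstream visualisation tools.
#'
#' BS3 crosslinks are conventionally validated at `d_max = 30` Angstrom
#' Calpha-Calpha. Unmapped links are excluded from the percentage
#' denominator and reported separately.
#'
#' @param mapped output of [map_crosslinks()]
#' @param d_max distance threshold in Angstrom (default 30)
#' @param score_norm_factor divisor for the exported scores (default 10)
#' @return an object of class `xl_validation`: list with `links` (the
#'   per-link tibble incl. `status`), `n_total`, `n_mapped`,
#'   `n_satisfied`, `n_violated`, `n_unmapped`, `percent_satisfied`
#'   (integer-rounded; `NA` if nothing mapped), `pair_counts` (tibble),
#'   `export` (tibble with normalised scores), `d_max`
#' @export
validate_crosslinks <- function(mapped, d_max = 30, score_norm_factor = 10) {
  stopifnot(d_max > 0)
  links <- mapped
  links$status <- dplyr::case_when(
    !links$mapped ~ "unmapped",
    links$distance <= d_max ~ "satisfied",
    TRUE ~ "violated"
  )
  n_total <- nrow(links)
  n_sat <- sum(links$status == "satisfied")
  n_vio <- sum(links$status == "violated")
  n_unm <- sum(links$status == "unmapped")
  pct <- if (n_sat + n_vio > 0) round(100 * n_sat / (n_sat + n_vio)) else NA_real_
  pair_counts <- links |>
    dplyr::mutate(
      sub_a = pmin(.data$protein1, .data$protein2),
      sub_b = pmax(.data$protein1, .data$protein2)) |>
    dplyr::count(.data$sub_a, .data$sub_b, name = "n")
  export <- links |>
    dplyr::mutate(norm_score = .data$score / score_norm_factor) |>
    dplyr::select(dplyr::all_of(c("protein1", "res1", "protein2", "res2")),
                  "norm_score", "distance", "status", "type")
  structure(
    list(links = links, n_total = n_total, n_mapped = n_sat + n_vio,
         n_satisfied = n_sat, n_violated = n_vio, n_unmapped = n_unm,
         percent_satisfied = pct, pair_counts = pair_counts,
         export = export, d_max = d_max,
         score_norm_factor = score_norm_factor),
    class = "xl_validation")
}

#' @export
print.xl_validation <- function(x, ...) {
  cat(sprintf("<xl_validation> %d links: %d satisfied, %d violated, %d unmapped (d_max %.1f A)\n",
              x$n_total, x$n_satisfied, x$n_violated, x$n_unmapped, x$d_max))
  if (!is.na(x$percent_satisfied)) {
    cat(sprintf("  %d%% of mapped links satisfied\n", x$percent_satisfied))
  }
  invisible(x)
}

#' Per-subunit-pair crosslink counts
#'
#' Symmetric count table of crosslinks between each unordered pair of
#' subunits (the bar-plot summary of a crosslink network). Row and column
#' sums equal per-subunit endpoint counts; the total equals the number of
#' links in the report.
#'
#' @param x an `xl_validation` object or a mapped-crosslink tibble
#' @param status optional status filter, e.g. `"satisfied"`
#' @return a tibble `sub_a`, `sub_b`, `n` (with `sub_a <= sub_b`)
#' @export
summarize_pairs <- function(x, status = NULL) {
  links <- if (inherits(x, "xl_validation")) x$links else x
  if (!is.null(status)) links <- links[links$status %in% status, ]
  links |>
    dplyr::mutate(
      sub_a = pmin(.data$protein1, .data$protein2),
      sub_b = pmax(.data$protein1, .data$protein2)) |>
    dplyr::count(.data$sub_a, .data$sub_b, name = "n")
}

#' Association between crosslink violation and model flexibility
#'
#' Tests whether violated crosslinks preferentially touch flexible
#' residues — the expectation that links incompatible with a rigid model
#' fall in segments the model ensemble itself marks as mobile. A residue
#' is "flexible" when its profile deviation exceeds the `q`-quantile of
#' the profile. The observed statistic is the fraction of violated links
#' with at least one flexible endpoint; the null distribution permutes
#' the satisfied/violated labels over mapped links (fixed counts), and
#' the p-value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' This statistic and its permutation null are this package's
#' formalisation of a qualitative observation; reports flag it as such.
#'
#' @param validation an `xl_validation` object
#' @param profile a `flex_profile` tibble (see [flexibility_profile()])
#' @param map [chain_map()] connecting link subunits to profile chains
#' @param q flexible-residue quantile (default 0.8)
#' @param n_perm number of permutations (>= 100; default 999)
#' @param seed RNG seed
#' @return a one-row tibble: `observed` (fraction), `p_value`,
#'   `n_violated`, `n_flexible_residues`, `q`, `n_perm`; `observed` is
#'   `NA` with a message when there are no violated links
#' @export
flexibility_association <- function(validation, profile,
                                    map = NULL, q = 0.8,
                                    n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 100)
  links <- validation$links[validation$links$status %in%
                              c("satisfied", "violated"), ]
  if (is.null(map)) {
    map <- tibble::tibble(subunit = unique(profile$chain),
                          chain = unique(profile$chain))
  }
  thr <- stats::quantile(profile$deviation, q, names = FALSE)
  flex_key <- paste(profile$chain[profile$deviation > thr],
                    profile$resno[profile$deviation > thr])
  sub_chain <- function(protein) map$chain[match(protein, map$subunit)]
  touches <- paste(sub_chain(links$protein1), links$res1) %in% flex_key |
    paste(sub_chain(links$protein2), links$res2) %in% flex_key
  n_vio <- sum(links$status == "violated")
  if (n_vio == 0) {
    message("no violated links; association statistic undefined")
    return(tibble::tibble(observed = NA_real_, p_value = NA_real_,
                          n_violated = 0L,
                          n_flexible_residues = length(flex_key),
                          q = q, n_perm = as.integer(n_perm)))
  }
  observed <- sum(touches & links$status == "violated") / n_vio
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- replicate(n_perm, {
    lab <- sample(links$status)
    sum(touches & lab == "violated") / n_vio
  })
  p <- (1 + sum(null >= observed - 1e-12)) / (1 + n_perm)
  tibble::tibble(observed = observed, p_value = p,
                 n_violated = as.integer(n_vio),
                 n_flexible_residues = length(flex_key),
                 q = q, n_perm = as.integer(n_perm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
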