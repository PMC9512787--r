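#' Rotation relating a mobile domain between two conformations
#'
#' Measures the hinge motion of a domain between two conformations of the
#' same assembly: the structures are first superposed on a fixed reference
#' selection, then the least-squares rotation of the mobile selection is
#' decomposed into an axis and an angle. This is how an opening/closing
#' clamp motion (e.g. a 23-degree clamp opening between two negative-stain
#' conformations) or the ~180-degree relative rotation of two
#' calponin-homology domains is quantified.
#'
#' With `center_mode = "centroid"` and an empty `ref_sel`, no reference
#' superposition is performed; instead both mobile domains are translated
#' so their centroids coincide before the rotation is measured (the
#' convention for comparing domain orientations "according to domain
#' centroids").
#'
#' @param a,b atom tables of the two conformations
#' @param ref_sel reference [selection()] (may be empty with
#'   `center_mode = "centroid"`)
#' @param mobile_sel mobile-domain [selection()]
#' @param map_a,map_b chain maps for `a` and `b` (default identity)
#' @param center_mode `"none"` or `"centroid"`
#' @return an object of class `hinge_measurement`: `angle_deg` in
#'   `[0, 180]`, unit `axis` (right-handed), `rmsd_ref` (reference fit,
#'   `NA` in centroid mode), `rmsd_mobile` (residual RMSD of the mobile
#'   domain after applying the recovered rotation)
#' @export
rotation_between <- function(a, b, ref_sel, mobile_sel,
                             map_a = identity_chain_map(a),
                             map_b = identity_chain_map(b),
                             center_mode = c("none", "centroid")) {
  center_mode <- match.arg(center_mode)

  matched_xyz <- function(s, sel, map) {
    res <- resolve_selection(s, sel, map, atoms = "CA")$atoms
    key <- paste(res$chain, res$resno, res$icode)
    list(xyz = coords(res), key = key)
  }
  pair_xyz <- function(sel) {
    pa <- matched_xyz(a, sel, map_a)
    pb <- matched_xyz(b, sel, map_b)
    shared <- intersect(pa$key, pb$key)
    if (length(shared) < 3) {
      stop("fewer than 3 shared residues in selection", call. = FALSE)
    }
    list(a = pa$xyz[match(shared, pa$key), , drop = FALSE],
         b = pb$xyz[match(shared, pb$key), , drop = FALSE])
  }

  rmsd_ref <- NA_real_
  if (nrow(ref_sel) > 0) {
    ref <- pair_xyz(ref_sel)
    fit <- kabsch(ref$b, ref$a)
    rmsd_ref <- fit$rmsd
    b <- apply_transform(b, fit$transform)
  } else if (center_mode != "centroid") {
    stop("ref_sel is empty; use center_mode = \"centroid\"", call. = FALSE)
  }

  mob <- pair_xyz(mobile_sel)
  if (center_mode == "centroid" && nrow(ref_sel) == 0) {
    mob$a <- sweep(mob$a, 2, colMeans(mob$a))
    mob$b <- sweep(mob$b, 2, colMeans(mob$b))
  }
  fit <- kabsch(mob$b, mob$a)
  aa <- rotation_angle_axis(t(fit$transform$R))
  # report the rotation taking conformation a's mobile domain onto b's
  structure(
    list(angle_deg = aa$angle, axis = aa$axis,
         rmsd_ref = rmsd_ref, rmsd_mobile = fit$rmsd,
         ref_sel = ref_sel, mobile_sel = mobile_sel,
         center_mode = center_mode),
    class = "hinge_measurement")
}

#' @export
print.hinge_measurement <- function(x, ...) {
  cat(sprintf("<hinge_measurement> %.2f deg about (%.3f, %.3f, %.3f)\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  reference fit rmsd: %s A, mobile residual rmsd: %.3f A\n",
              ifelse(is.na(x$rmsd_ref), "-", sprintf("%.3f", x$rmsd_ref)),
              x$rmsd_mobile))
  invisible(x)
}

#' Splice a composite model from several source models
#'
#' Builds one model from complementary segments of several source models —
#' e.g. joining a tetramer model with an overlapping subcomplex model by
#' retaining complementary residue ranges from each, deleting hinge-region
#' residues, and applying per-source rigid placements obtained from
#' density docking.
#'
#' @param recipe a list with `splices` — tibble `model_id`, `subunit`,
#'   `start`, `end` — and optional `deletions` — a [selection()] tibble
#'   applied after splicing
#' @param models named list of atom tables, names matching
#'   `recipe$splices$model_id`
#' @param placements optional named list of [rigid_transform()] per
#'   model id (default identity)
#' @param maps optional named list of chain maps per model id (default
#'   identity per model)
#' @return an [atom_tbl()] containing exactly the union of spliced
#'   residues minus deletions, chain ids preserved
#' @export
splice_composite <- function(recipe, models, placements = list(),
                             maps = list()) {
  sp <- tibble::as_tibble(recipe$splices)
  stopifnot(all(c("model_id", "subunit", "start", "end") %in% names(sp)))
  miss <- setdiff(unique(sp$model_id), names(models))
  if (length(miss) > 0) {
    stop("recipe references missing model(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # residue-level disjointness across splices, per (subunit, resno)
  res_sets <- purrr::pmap(sp, function(model_id, subunit, start, end) {
    tibble::tibble(subunit = subunit, resno = seq.int(start, end))
  })
  all_res <- dplyr::bind_rows(res_sets)
  dup <- all_res[duplicated(paste(all_res$subunit, all_res$resno)), ]
  if (nrow(dup) > 0) {
    stop("overlapping splices for: ",
         paste(utils::head(paste0(dup$subunit, ":", dup$resno), 10),
               collapse = ", "), call. = FALSE)
  }
  pieces <- purrr::pmap(sp, function(model_id, subunit, start, end) {
    s <- models[[model_id]]
    map <- maps[[model_id]] %||% identity_chain_map(s)
    sel <- tibble::tibble(subunit = subunit, start = start, end = end)
    piece <- resolve_selection(s, sel, map, atoms = "all")$atoms
    tf <- placements[[model_id]]
    if (!is.null(tf)) piece <- apply_transform(piece, tf)
    piece
  })
  out <- dplyr::bind_rows(pieces)
  del <- recipe$deletions
  if (!is.null(del) && nrow(del) > 0) {
    for (i in seq_len(nrow(del))) {
      hit <- out$chain == del$subunit[i] &
        out$resno >= del$start[i] & out$resno <= del$end[i]
      if (!any(hit)) {
        warning("deletion ", del$subunit[i], " ", del$start[i], "-",
                del$end[i], " matches no spliced residue", call. = FALSE)
      }
      out <- out[!hit, ]
    }
  }
  out$model <- 1L
  key <- paste(out$chain, out$resno, out$icode, out$elety)
  if (anyDuplicated(key)) {
    stop("composite contains duplicate atoms; check chain maps",
         call. = FALSE)
  }
  atom_tbl(dplyr::arrange(out, .data$chain, .data$resno, .data$icode,
                          .data$elety))
}

#' The splice recipe joining the TIII and arm+TII tetramer models
#'
#' The composite holocomplex model retains HAUS3 198-364 and HAUS5
#' 275-419 from the model of the H3/H5 arm in complex with TII, and the
#' remaining HAUS3/HAUS5 segments plus HAUS1 and HAUS4 from the TIII
#' model; hinge-region residues and the disordered HAUS6 tail are
#' deleted when the N-clamp is docked separately.
#'
#' @param tiii_id,arm_id model ids used in the returned recipe
#' @param haus3_range,haus5_range full modelled ranges of HAUS3/HAUS5 in
#'   the TIII model (defaults: the predicted-model ranges 96-434 and
#'   80-489)
#' @return a recipe list for [splice_composite()]
#' @export
augmin_splice_recipe <- function(tiii_id = "tiii", arm_id = "arm_tii",
                                 haus3_range = c(96, 434),
                                 haus5_range = c(80, 489)) {
  splices <- tibble::tribble(
    ~model_id, ~subunit, ~start, ~end,
    arm_id, "HAUS3", 198L, 364L,
    arm_id, "HAUS5", 275L, 419L,
    tiii_id, "HAUS3", haus3_range[1], 197L,
    tiii_id, "HAUS3", 365L, haus3_range[2],
    tiii_id, "HAUS5", haus5_range[1], 274L,
    tiii_id, "HAUS5", 420L, haus5_range[2]
  )
  list(splices = splices, deletions = NULL)
}
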