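#' Residue-range selections
#'
#' A selection is a tibble with columns `subunit`, `start`, `end`, each row
#' one inclusive author-numbered residue range. `selection()` builds one
#' from named ranges; `parse_selection()` parses the compact notation used
#' throughout the package, e.g. `"HAUS2 1-117; HAUS6 1-267"` (several
#' ranges of one subunit may be comma-separated:
#' `"HAUS3 198-242, 364-392"`).
#'
#' @param ... named ranges, each a length-2 integer vector, e.g.
#'   `HAUS2 = c(1, 117)`
#' @return a tibble with columns `subunit`, `start`, `end`
#' @export
selection <- function(...) {
  args <- list(...)
  if (length(args) == 0) {
    return(tibble::tibble(subunit = character(), start = integer(),
                          end = integer()))
  }
  if (is.null(names(args)) || any(names(args) == "")) {
    stop("selection() arguments must be named by subunit", call. = FALSE)
  }
  out <- purrr::imap_dfr(args, function(rng, nm) {
    if (length(rng) != 2) stop("range for ", nm, " must have length 2",
                               call. = FALSE)
    tibble::tibble(subunit = nm, start = as.integer(rng[1]),
                   end = as.integer(rng[2]))
  })
  validate_selection(out)
}

#' @rdname selection
#' @param text selection string, `"SUBUNIT a-b[, c-d]; SUBUNIT2 e-f"`
#' @export
parse_selection <- function(text) {
  terms <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  out <- purrr::map_dfr(terms, function(term) {
    m <- regmatches(term, regexec("^(\\S+)\\s+(.+)$", term))[[1]]
    if (length(m) != 3) stop("cannot parse selection term '", term, "'",
                             call. = FALSE)
    ranges <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    purrr::map_dfr(ranges, function(r) {
      ab <- regmatches(r, regexec("^(\\d+)\\s*-\\s*(\\d+)$", r))[[1]]
      if (length(ab) != 3) stop("cannot parse range '", r, "' in '", term,
                                "'", call. = FALSE)
      tibble::tibble(subunit = m[2], start = as.integer(ab[2]),
                     end = as.integer(ab[3]))
    })
  })
  validate_selection(out)
}

validate_selection <- function(sel) {
  sel <- tibble::as_tibble(sel)[, c("subunit", "start", "end")]
  if (any(sel$start > sel$end)) {
    stop("selection has start > end", call. = FALSE)
  }
  sel
}

#' Subunit-to-chain maps
#'
#' Maps subunit names (e.g. `HAUS3`) to one or more chain identifiers of a
#' model. Many-to-one is allowed (a subunit present in two copies).
#'
#' @param ... named chain ids, e.g. `HAUS1 = "A"`, `HAUS3 = c("C", "D")`
#' @return a tibble with columns `subunit`, `chain`
#' @export
chain_map <- function(...) {
  args <- list(...)
  if (length(args) == 0) {
    return(tibble::tibble(subunit = character(), chain = character()))
  }
  purrr::imap_dfr(args, function(ch, nm) {
    tibble::tibble(subunit = nm, chain = as.character(ch))
  })
}

#' Identity chain map of a structure
#'
#' For models whose chains are already named by subunit (all synthetic
#' models in this package), the chain map is the identity.
#'
#' @param s atom table
#' @return a `chain_map` tibble
#' @export
identity_chain_map <- function(s) {
  ch <- unique(s$chain)
  tibble::tibble(subunit = ch, chain = ch)
}

map_chains <- function(map, subunit) {
  out <- map$chain[map$subunit == subunit]
  if (length(out) == 0) {
    stop("subunit '", subunit, "' not covered by the chain map",
         call. = FALSE)
  }
  out
}

#' Resolve a selection against a structure
#'
#' Expands a residue-range selection to concrete atom rows of a model and
#' reports requested residues that the model does not contain. Atoms are
#' returned in deterministic order (chain, residue number, insertion code,
#' atom name); missing residues are reported, never silently dropped.
#'
#' @param s atom table (single model; for multi-model tables the first
#'   model is used)
#' @param sel a [selection()] tibble
#' @param map a [chain_map()] tibble covering every subunit in `sel`
#' @param atoms `"CA"` (default) or `"all"`
#' @return a list with `atoms` (atom table subset) and `missing` (tibble of
#'   `subunit`, `chain`, `resno` requested but absent)
#' @export
resolve_selection <- function(s, sel, map = identity_chain_map(s),
                              atoms = c("CA", "all")) {
  atoms <- match.arg(atoms)
  sm <- dplyr::filter(s, .data$model == min(.data$model))
  if (atoms == "CA") sm <- dplyr::filter(sm, .data$elety == "CA")
  hits <- list(); miss <- list()
  for (i in seq_len(nrow(sel))) {
    chains <- map_chains(map, sel$subunit[i])
    want <- seq.int(sel$start[i], sel$end[i])
    for (ch in chains) {
      rows <- dplyr::filter(sm, .data$chain == ch, .data$resno %in% want)
      hits[[length(hits) + 1]] <- rows
      absent <- setdiff(want, unique(rows$resno))
      if (length(absent) > 0) {
        miss[[length(miss) + 1]] <- tibble::tibble(
          subunit = sel$subunit[i], chain = ch, resno = as.integer(absent))
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, .data$chain, .data$resno, .data$icode,
                        .data$elety)
  missing <- if (length(miss) > 0) {
    dplyr::distinct(dplyr::bind_rows(miss))
  } else {
    tibble::tibble(subunit = character(), chain = character(),
                   resno = integer())
  }
  if (nrow(out) == 0) {
    stop("selection resolves to no atoms", call. = FALSE)
  }
  list(atoms = out, missing = missing)
}

#' Fixed selections for the augmin TII/TIII analysis
#'
#' The residue-range constants used throughout the augmin holocomplex
#' analysis: the TII N-clamp and C-clamp superposition ranges, the
#' HAUS3/HAUS5 arm ranges used to join the tetramer models, the rigid
#' N-clamp body used for docking, the hinge-region deletions applied when
#' splicing the holocomplex, and the disordered HAUS6 tail removal.
#'
#' @return a named list of selection tibbles
#' @export
augmin_selections <- function() {
  list(
    n_clamp = parse_selection("HAUS2 1-117; HAUS6 1-267; HAUS7 1-270; HAUS8 155-260"),
    c_clamp = parse_selection("HAUS2 118-222; HAUS6 268-398; HAUS7 271-348; HAUS8 261-367"),
    h3h5_arm = parse_selection("HAUS3 198-242, 364-392; HAUS5 172-275, 419-446"),
    n_clamp_rigid = parse_selection("HAUS2 1-114; HAUS6 1-263; HAUS7 1-261; HAUS8 155-259"),
    hinge_deletions = parse_selection("HAUS2 115-119; HAUS6 264-275; HAUS7 262-270; HAUS8 260-269"),
    haus6_tail = parse_selection("HAUS6 398-478")
  )
}
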