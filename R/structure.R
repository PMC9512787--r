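#' Atom tables
#'
#' `augminr` represents an atomic model as a tibble of atom records
#' ("atom table"), one row per atom, with author residue numbering kept
#' exactly as read from the file. Columns:
#'
#' * `model`  — integer model number (multi-model files yield several)
#' * `chain`  — chain identifier (also the subunit name for synthetic models)
#' * `resno`  — author residue number (integer, 1-based)
#' * `icode`  — insertion code (`""` when absent)
#' * `resid`  — 3-letter residue name
#' * `elety`  — atom name (e.g. `"CA"`)
#' * `elesy`  — element symbol
#' * `x`, `y`, `z` — coordinates in Angstrom
#'
#' @param df a data frame with the columns above (missing `model`, `icode`,
#'   `resid`, `elesy` are filled with defaults)
#' @return a tibble of class `atom_tbl`
#' @export
atom_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"model" %in% names(df)) df$model <- 1L
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"resid" %in% names(df)) df$resid <- "ALA"
  if (!"elety" %in% names(df)) df$elety <- "CA"
  if (!"elesy" %in% names(df)) df$elesy <- substr(df$elety, 1, 1)
  need <- c("model", "chain", "resno", "icode", "resid", "elety", "elesy",
            "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  df$model <- as.integer(df$model)
  df$resno <- as.integer(df$resno)
  df$icode[is.na(df$icode)] <- ""
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  key <- paste(df$model, df$chain, df$resno, df$icode, df$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (model, chain, resno, icode, atom) records in atom table",
         call. = FALSE)
  }
  class(df) <- c("atom_tbl", class(tibble::tibble()))
  df
}

#' @export
print.atom_tbl <- function(x, ...) {
  nm <- dplyr::n_distinct(x$model)
  cat(sprintf("<atom_tbl> %d atoms, %d chain(s), %d model(s)\n",
              nrow(x), dplyr::n_distinct(x$chain), nm))
  NextMethod()
}

#' Coordinate matrix of an atom table
#'
#' @param s atom table
#' @return an N x 3 numeric matrix
#' @export
coords <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

#' Replace the coordinates of an atom table
#'
#' @param s atom table
#' @param xyz N x 3 matrix in row order of `s`
#' @return the atom table with new coordinates
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]
  s$y <- xyz[, 2]
  s$z <- xyz[, 3]
  s
}

#' Restrict an atom table to Calpha atoms
#'
#' @param s atom table
#' @return atom table with only `CA` rows, ordered by (chain, resno, icode)
#' @export
ca_atoms <- function(s) {
  out <- dplyr::arrange(dplyr::filter(s, .data$elety == "CA"),
                        .data$model, .data$chain, .data$resno, .data$icode)
  out
}

# Convert a bio3d pdb object (single model) to a tibble of atom rows.
# Alternate locations: keep the highest occupancy; ties keep the first
# record encountered.
bio3d_to_tbl <- function(pdb, model = 1L) {
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- rep(TRUE, nrow(at))
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -occ, seq_len(nrow(at)))
    dup <- duplicated(key[ord])
    keep <- logical(nrow(at))
    keep[ord] <- !dup
  }
  at <- at[keep, , drop = FALSE]
  icode <- at$insert
  icode[is.na(icode)] <- ""
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- substr(trimws(at$elety), 1, 1)
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  ch <- at$chain
  ch[is.na(ch)] <- " "
  tibble::tibble(
    model = as.integer(model), chain = ch, resno = as.integer(at$resno),
    icode = icode, resid = at$resid, elety = trimws(at$elety),
    elesy = trimws(elesy), x = at$x, y = at$y, z = at$z
  )
}

#' Read an atomic structure
#'
#' Reads a PDB or mmCIF file into an atom table. Author residue numbering
#' and insertion codes are preserved; each `MODEL` block of a multi-model
#' PDB file becomes one value of the `model` column. Alternate locations
#' keep the highest-occupancy copy (ties: first encountered).
#'
#' @param path file path
#' @param format `"pdb"` or `"cif"`; default guessed from the extension
#' @return an [atom_tbl]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "cif") {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e) stop("cannot parse mmCIF file '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    out <- bio3d_to_tbl(pdb)
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("cannot parse PDB file '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || nmod <= 1) {
      out <- bio3d_to_tbl(pdb)
    } else {
      base <- bio3d_to_tbl(pdb)
      out <- purrr::map_dfr(seq_len(nmod), function(m) {
        xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
        b <- base
        b$model <- as.integer(m)
        # bio3d drops altloc duplicates from $atom but keeps them in $xyz
        # only when read without filtering; row counts match here
        b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
        b
      })
    }
  }
  if (nrow(out) == 0) stop("structure in '", path, "' is empty", call. = FALSE)
  atom_tbl(out)
}

#' Write an atomic structure to PDB
#'
#' Writes an atom table as a PDB file (one `MODEL` block per model when the
#' table has several). Round-trips through [read_structure()].
#'
#' @param s atom table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path) {
  if (nrow(s) == 0) stop("refusing to write an empty structure", call. = FALSE)
  if (any(s$resno > 9999 | s$resno < -999)) {
    stop("residue numbers outside PDB field width", call. = FALSE)
  }
  # the PDB chain field is one character: map longer (e.g. subunit-style
  # "S1") chain ids deterministically onto single letters
  if (any(nchar(s$chain) > 1)) {
    pool <- c(LETTERS, letters, 0:9)
    ch <- sort(unique(s$chain))
    if (length(ch) > length(pool)) {
      stop("too many chains for PDB output", call. = FALSE)
    }
    lut <- setNames(pool[seq_along(ch)], ch)
    warning("multi-character chain id(s) remapped for PDB output: ",
            paste(ch, "->", lut[ch], collapse = ", "), call. = FALSE)
    s$chain <- unname(lut[s$chain])
  }
  models <- sort(unique(s$model))
  write_one <- function(sm, file) {
    bio3d::write.pdb(
      file = file,
      xyz = as.vector(t(coords(sm))),
      resno = sm$resno,
      resid = sm$resid,
      eleno = seq_len(nrow(sm)),
      elety = sm$elety,
      chain = sm$chain,
      insert = ifelse(sm$icode == "", NA, sm$icode),
      elesy = sm$elesy
    )
  }
  if (length(models) == 1) {
    write_one(s, path)
  } else {
    lines <- character(0)
    for (m in models) {
      tmp <- tempfile(fileext = ".pdb")
      write_one(s[s$model == m, ], tmp)
      body <- readLines(tmp)
      body <- body[!grepl("^END", body)]
      unlink(tmp)
      lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' One-letter amino-acid sequence of a chain
#'
#' @param s atom table
#' @param chain chain identifier
#' @return a single string (Calpha-bearing residues, in residue order)
#' @export
chain_sequence <- function(s, chain) {
  ca <- ca_atoms(dplyr::filter(s, .data$chain == !!chain, .data$model == min(.data$model)))
  if (nrow(ca) == 0) stop("chain '", chain, "' has no Calpha atoms", call. = FALSE)
  paste(bio3d::aa321(ca$resid), collapse = "")
}
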