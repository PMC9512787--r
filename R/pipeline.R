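#' Run the integrative analysis pipeline
#'
#' Config-driven orchestration of the full analysis: ensemble alignment
#' and flexibility profiling, crosslink deduplication / filtering /
#' mapping / validation, violation-flexibility association, rigid-body
#' density fitting, composite-model splicing, and hinge measurement.
#' Every stage is optional; the report contains only the stages that
#' ran. Deterministic for fixed inputs and seeds.
#'
#' The configuration is a named list (or a YAML file path with the same
#' structure). Recognised entries:
#'
#' * `stages` — character subset of `c("flexibility", "crosslinks",
#'   "association", "fit", "splice", "hinge")`; default: every stage
#'   whose inputs are present
#' * `ensemble` — list of atom tables, or a directory of PDB files
#' * `core` — core [selection()] (or selection string) for alignment
#' * `model` — atom table or PDB path: the validation target model
#' * `crosslinks` — crosslink tibble or TSV/CSV path
#' * `chains` — named list, subunit -> chain id(s) (default identity)
#' * `params` — `d_max` (30), `score_min` (250), `score_norm_factor`
#'   (10), `resolution` (8), `flex_quantile` (0.8), `n_perm` (999)
#' * `fit` — list: `map` ([density_map()] or MRC path), `model`
#'   (defaults to `model`), `search` (see [rigid_fit()])
#' * `splice` — list: `recipe`, `models`, optional `placements`
#' * `hinge` — list: `a`, `b` (atom tables or paths), `ref_sel`,
#'   `mobile_sel` (selections or strings), `center_mode`
#' * `seed` — RNG seed for the permutation test (default 1)
#' * `output_dir` — if set, TSV/JSON/PDB outputs are written there
#'
#' @param config named list or YAML file path
#' @return an object of class `report_bundle` (named list of stage
#'   results plus a `provenance` block)
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  p <- cfg$params %||% list()
  d_max <- p$d_max %||% 30
  score_min <- p$score_min %||% 250
  norm_f <- p$score_norm_factor %||% 10
  resolution <- p$resolution %||% 8
  flex_q <- p$flex_quantile %||% 0.8
  n_perm <- p$n_perm %||% 999
  seed <- cfg$seed %||% 1

  as_structure <- function(x) {
    if (is.character(x)) read_structure(x) else x
  }
  as_sel <- function(x) {
    if (is.character(x)) parse_selection(x) else tibble::as_tibble(x)
  }
  cmap <- if (!is.null(cfg$chains)) {
    do.call(chain_map, as.list(cfg$chains))
  } else NULL

  ensemble <- NULL
  if (!is.null(cfg$ensemble)) {
    ensemble <- if (is.character(cfg$ensemble) &&
                    length(cfg$ensemble) == 1 && dir.exists(cfg$ensemble)) {
      purrr::map(sort(list.files(cfg$ensemble, "\\.pdb$",
                                 full.names = TRUE)), read_structure)
    } else if (is.character(cfg$ensemble)) {
      purrr::map(cfg$ensemble, read_structure)
    } else {
      cfg$ensemble
    }
  }
  model <- if (!is.null(cfg$model)) as_structure(cfg$model) else NULL

  want <- cfg$stages %||% c(
    if (!is.null(ensemble)) "flexibility",
    if (!is.null(cfg$crosslinks) && !is.null(model)) c("crosslinks",
      if (!is.null(ensemble)) "association"),
    if (!is.null(cfg$fit)) "fit",
    if (!is.null(cfg$splice)) "splice",
    if (!is.null(cfg$hinge)) "hinge")
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  profile <- NULL
  if ("flexibility" %in% want) {
    report$flexibility <- stage("flexibility", {
      cm <- cmap %||% identity_chain_map(ensemble[[1]])
      aligned <- align_ensemble(ensemble,
                                core = if (!is.null(cfg$core)) as_sel(cfg$core),
                                map = cm)
      prof <- flexibility_profile(aligned$ensemble, mode = "ensemble_rmsd")
      extreme <- flexibility_profile(aligned$ensemble, mode = "extreme_pair")
      list(per_model_rmsd = aligned$rmsd, profile = prof,
           extreme_profile = extreme,
           extreme_pair = attr(extreme, "extreme_pair"))
    })
    profile <- report$flexibility$profile
  }

  validation <- NULL
  if ("crosslinks" %in% want) {
    report$crosslinks <- stage("crosslinks", {
      xl <- cfg$crosslinks
      if (is.character(xl)) xl <- read_crosslinks(xl)
      filtered <- dedup_and_filter(xl, score_min = score_min)
      cm <- cmap %||% identity_chain_map(model)
      mapped <- map_crosslinks(filtered, model, cm)
      v <- validate_crosslinks(mapped, d_max = d_max,
                               score_norm_factor = norm_f)
      if (v$n_unmapped > 0) {
        warning(v$n_unmapped, " crosslink(s) unmapped on the model",
                call. = FALSE)
      }
      list(n_input = nrow(xl), n_filtered = nrow(filtered),
           validation = v,
           summary = glance(v),
           pair_counts = v$pair_counts)
    })
    validation <- report$crosslinks$validation
  }

  if ("association" %in% want) {
    report$association <- stage("association", {
      if (is.null(validation) || is.null(profile)) {
        stop("association requires the crosslink and flexibility stages")
      }
      out <- flexibility_association(validation, profile, map = cmap,
                                     q = flex_q, n_perm = n_perm,
                                     seed = seed)
      out$note <- paste("exploratory statistic: quantile-thresholded",
                        "flexibility with label-permutation null")
      out
    })
  }

  if ("fit" %in% want) {
    report$fit <- stage("fit", {
      mp <- cfg$fit$map
      if (is.character(mp)) mp <- read_map(mp)
      fs <- cfg$fit$model %||% model
      fs <- as_structure(fs)
      fit <- rigid_fit(fs, mp, resolution = resolution,
                       search = cfg$fit$search)
      list(result = fit, summary = glance(fit))
    })
  }

  if ("splice" %in% want) {
    report$splice <- stage("splice", {
      models <- purrr::map(cfg$splice$models, as_structure)
      composite <- splice_composite(cfg$splice$recipe, models,
                                    placements = cfg$splice$placements %||% list())
      list(composite = composite, n_atoms = nrow(composite))
    })
  }

  if ("hinge" %in% want) {
    report$hinge <- stage("hinge", {
      h <- cfg$hinge
      hm <- rotation_between(as_structure(h$a), as_structure(h$b),
                             ref_sel = as_sel(h$ref_sel %||% selection()),
                             mobile_sel = as_sel(h$mobile_sel),
                             center_mode = h$center_mode %||% "none")
      list(measurement = hm, summary = tidy(hm))
    })
  }

  report$provenance <- list(
    package = "augminr",
    version = as.character(utils::packageVersion("augminr")),
    seed = seed,
    params = list(d_max = d_max, score_min = score_min,
                  score_norm_factor = norm_f, resolution = resolution,
                  flex_quantile = flex_q, n_perm = n_perm),
    stages = want,
    config_digest = config_digest(cfg)
  )
  class(report) <- "report_bundle"

  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  if (!is.null(x$crosslinks)) print(x$crosslinks$validation)
  if (!is.null(x$hinge)) print(x$hinge$measurement)
  if (!is.null(x$fit)) print(x$fit$result)
  invisible(x)
}

# write the tabular/numeric parts of a report bundle to a directory
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- report_numbers(report)
  jsonlite::write_json(num, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$flexibility)) {
    readr::write_tsv(report$flexibility$profile,
                     file.path(dir, "flexibility_profile.tsv"))
  }
  if (!is.null(report$crosslinks)) {
    readr::write_tsv(report$crosslinks$validation$export,
                     file.path(dir, "crosslinks_validated.tsv"))
    readr::write_tsv(report$crosslinks$pair_counts,
                     file.path(dir, "crosslink_pair_counts.tsv"))
  }
  if (!is.null(report$splice)) {
    write_structure(report$splice$composite,
                    file.path(dir, "composite_model.pdb"))
  }
  invisible(dir)
}

# flat numeric summary of a report bundle (used for the JSON report and
# determinism checks); percentages to integers, angles to 0.1 deg,
# distances/rmsd to 0.01 A
report_numbers <- function(report) {
  out <- list()
  if (!is.null(report$crosslinks)) {
    s <- report$crosslinks$summary
    out$crosslinks <- list(
      n_input = report$crosslinks$n_input,
      n_filtered = report$crosslinks$n_filtered,
      n_mapped = s$n_mapped, n_satisfied = s$n_satisfied,
      n_violated = s$n_violated, n_unmapped = s$n_unmapped,
      percent_satisfied = s$percent_satisfied)
  }
  if (!is.null(report$flexibility)) {
    out$flexibility <- list(
      n_residues = nrow(report$flexibility$profile),
      max_deviation = round(max(report$flexibility$profile$deviation), 2),
      extreme_pair = unlist(report$flexibility$extreme_pair[c("i", "j")]))
  }
  if (!is.null(report$association)) {
    out$association <- list(
      observed = report$association$observed,
      p_value = report$association$p_value)
  }
  if (!is.null(report$fit)) {
    out$fit <- list(cc = round(report$fit$result$cc, 4))
  }
  if (!is.null(report$splice)) {
    out$splice <- list(n_atoms = report$splice$n_atoms)
  }
  if (!is.null(report$hinge)) {
    out$hinge <- list(
      angle_deg = round(report$hinge$measurement$angle_deg, 1),
      axis = round(report$hinge$measurement$axis, 4))
  }
  out$provenance <- report$provenance[c("version", "seed", "params",
                                        "config_digest")]
  out
}
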