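#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns a per-item tibble, `glance()`
#' a one-row summary.
#'
#' @param x an `xl_validation`, `hinge_measurement` or `fit_result`
#' @param ... unused
#' @return a tibble
#' @name augminr-tidiers
NULL

#' @rdname augminr-tidiers
#' @export
tidy.xl_validation <- function(x, ...) {
  tibble::as_tibble(x$links)
}

#' @rdname augminr-tidiers
#' @export
glance.xl_validation <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_mapped = x$n_mapped,
    n_satisfied = x$n_satisfied, n_violated = x$n_violated,
    n_unmapped = x$n_unmapped, percent_satisfied = x$percent_satisfied,
    d_max = x$d_max)
}

#' @rdname augminr-tidiers
#' @export
tidy.hinge_measurement <- function(x, ...) {
  tibble::tibble(
    angle_deg = x$angle_deg,
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    rmsd_ref = x$rmsd_ref, rmsd_mobile = x$rmsd_mobile,
    center_mode = x$center_mode)
}

#' @rdname augminr-tidiers
#' @export
glance.hinge_measurement <- function(x, ...) {
  tidy.hinge_measurement(x)
}

#' @rdname augminr-tidiers
#' @export
tidy.fit_result <- function(x, ...) {
  x$trace
}

#' @rdname augminr-tidiers
#' @export
glance.fit_result <- function(x, ...) {
  aa <- rotation_angle_axis(x$transform$R)
  tibble::tibble(
    cc = x$cc, cc_identity = x$cc_identity,
    rotation_deg = aa$angle,
    shift = sqrt(sum(x$transform$t^2)),
    resolution = x$resolution)
}
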