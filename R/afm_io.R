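#' Write force curves to CSV with a YAML metadata sidecar
#'
#' Long-format CSV with columns `curve_id`, `z_um`, `force_nN`; probe
#' radius, Poisson's ratio and spring constant go to `<path>.yaml`.
#'
#' @param curves List of [force_curve()] objects (named or auto-numbered).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curves, path) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  ids <- names(curves) %||% paste0("curve", seq_along(curves))
  if (is.null(names(curves))) names(curves) <- ids
  tab <- do.call(rbind, lapply(ids, function(id) {
    fc <- curves[[id]]
    data.frame(curve_id = id, z_um = fc$z, force_nN = fc$force)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- lapply(curves, function(fc) {
    list(probe_radius_um = fc$probe_radius, poisson_nu = fc$poisson_nu,
         spring_constant_pN_nm = if (is.na(fc$spring_constant)) NULL
                                 else fc$spring_constant)
  })
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Parse force curves from CSV
#'
#' Accepts either `z_um` + `force_nN` columns, or `z_um` + `deflection_nm`
#' plus a spring constant (from the sidecar or `default_meta`), in which
#' case `force_nN = k[pN/nm] * deflection[nm] / 1000`. A `curve_id` column
#' separates multiple curves; without it the file is one curve. Curves with
#' non-monotone `z` or missing columns are rejected individually with a
#' recorded reason, never silently dropped.
#'
#' @param path CSV file path; `<path>.yaml` is read as sidecar metadata when
#'   present.
#' @param default_meta List of fallback metadata (`probe_radius_um`,
#'   `poisson_nu`, `spring_constant_pN_nm`).
#' @return List with `curves` (named list of [force_curve()]) and
#'   `rejected` (data frame `curve_id`, `reason`).
#' @export
parse_force_curves <- function(path, default_meta = list()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".yaml")
  meta_all <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (!"curve_id" %in% names(tab)) tab$curve_id <- "curve1"
  if (!"z_um" %in% names(tab)) stop("missing z_um column", call. = FALSE)
  curves <- list()
  rejected <- data.frame(curve_id = character(), reason = character())
  for (id in unique(tab$curve_id)) {
    sub <- tab[tab$curve_id == id, , drop = FALSE]
    meta <- utils::modifyList(default_meta, meta_all[[id]] %||% list())
    reason <- NULL
    if ("force_nN" %in% names(sub)) {
      force <- sub$force_nN
    } else if ("deflection_nm" %in% names(sub)) {
      k <- meta$spring_constant_pN_nm
      if (is.null(k)) reason <- "deflection given but no spring constant"
      else force <- k * sub$deflection_nm / 1000   # pN -> nN
    } else {
      reason <- "missing force_nN or deflection_nm column"
    }
    if (is.null(reason) && any(diff(sub$z_um) <= 0)) {
      reason <- "z not strictly increasing"
    }
    if (is.null(reason)) {
      curves[[id]] <- force_curve(
        sub$z_um, force,
        probe_radius = meta$probe_radius_um %||% 2.5,
        poisson_nu = meta$poisson_nu %||% 0.4,
        spring_constant = meta$spring_constant_pN_nm %||% NA_real_)
    } else {
      rejected <- rbind(rejected, data.frame(curve_id = id, reason = reason))
    }
  }
  list(curves = curves, rejected = rejected)
}
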