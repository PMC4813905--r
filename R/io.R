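# Configuration parsing and result serialization. Configs are YAML or JSON;
# every dimensioned quantity must carry a unit suffix ("3500 um", "1.9 GPa")
# to keep micrometre/metre mistakes out of this domain.

.unit_scale <- c(m = 1, mm = 1e-3, um = 1e-6, GPa = 1e9, MPa = 1e6,
                 kPa = 1e3, Pa = 1, deg = 1)

parse_quantity <- function(x, expect = c("length", "pressure", "angle"),
                           key = "") {
  expect <- match.arg(expect)
  if (is.numeric(x))
    pf_stop("pf_unit_error", "'%s' must carry a unit suffix (e.g. \"3500 um\")", key)
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[1]))) ||
      !parts[2] %in% names(.unit_scale))
    pf_stop("pf_unit_error", "cannot parse quantity '%s' for '%s'", x, key)
  ok <- switch(expect,
               length = parts[2] %in% c("m", "mm", "um"),
               pressure = parts[2] %in% c("GPa", "MPa", "kPa", "Pa"),
               angle = parts[2] == "deg")
  if (!ok) pf_stop("pf_unit_error", "unit '%s' invalid for %s '%s'",
                   parts[2], expect, key)
  as.numeric(parts[1]) * .unit_scale[[parts[2]]]
}

.config_keys <- list(
  probe = c("material", "width", "thickness", "length", "shape", "diameter",
            "stiffness"),
  coating = c("material", "thickness", "width", "length", "bevel_angle",
              "stiffness"),
  tissue = c("preset", "small_strain_stiffness", "deletion_threshold",
             "friction", "ogden_alpha", "bulk_modulus"),
  solver = c("mesh", "bc", "backend", "max_depth"))

#' Parse a run configuration file
#'
#' Reads a YAML or JSON config describing an assembly, tissue and solver
#' controls, validates it against the schema (unknown keys are rejected;
#' dimensioned values need unit suffixes) and fills defaults: deletion
#' threshold 0.05, friction 0.3, fixed-pinned boundary condition, default
#' mesh.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A `pf_config` with `assembly`, `tissue`, `solver`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) pf_stop("pf_io_error", "config '%s' not found", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  bad <- setdiff(names(raw), c(names(.config_keys)))
  if (length(bad))
    pf_stop("pf_config_error", "unknown config sections: %s", paste(bad, collapse = ", "))
  for (sec in names(.config_keys)) {
    extra <- setdiff(names(raw[[sec]]), .config_keys[[sec]])
    if (length(extra))
      pf_stop("pf_config_error", "unknown keys in '%s': %s", sec,
              paste(extra, collapse = ", "))
  }
  if (is.null(raw$probe)) pf_stop("pf_config_error", "config needs a 'probe' section")
  lib <- material_library()
  pr <- raw$probe
  pmat <- if (!is.null(pr$stiffness))
    material("probe_custom", parse_quantity(pr$stiffness, "pressure", "probe.stiffness"),
             1289, 0.45)
  else resolve_material(pr$material %||% "parylene_c", lib)
  q <- function(sec, key, what) parse_quantity(raw[[sec]][[key]], what,
                                               paste(sec, key, sep = "."))
  probe <- if (!is.null(pr$shape) && pr$shape == "circular") {
    probe_spec(length = m_to_um(q("probe", "length", "length")),
               material = pmat, shape = "circular",
               diameter = m_to_um(q("probe", "diameter", "length")))
  } else {
    probe_spec(width = m_to_um(q("probe", "width", "length")),
               thickness = m_to_um(q("probe", "thickness", "length")),
               length = m_to_um(q("probe", "length", "length")),
               material = pmat)
  }
  coating <- NULL
  if (!is.null(raw$coating)) {
    co <- raw$coating
    cmat <- if (!is.null(co$stiffness))
      material("coating_custom", parse_quantity(co$stiffness, "pressure", "coating.stiffness"),
               1290, 0.42)
    else resolve_material(co$material %||% "coating", lib)
    coating <- coating_spec(
      thickness = m_to_um(q("coating", "thickness", "length")),
      width = m_to_um(q("coating", "width", "length")),
      length = m_to_um(q("coating", "length", "length")),
      bevel_angle = if (!is.null(co$bevel_angle))
        parse_quantity(co$bevel_angle, "angle", "coating.bevel_angle") else 45,
      material = cmat)
  }
  ti <- raw$tissue %||% list()
  targs <- list(preset = ti$preset %||% "brain",
                deletion_threshold = ti$deletion_threshold %||% 0.05,
                friction = ti$friction %||% 0.3)
  if (!is.null(ti$small_strain_stiffness))
    targs$small_strain_stiffness <-
      parse_quantity(ti$small_strain_stiffness, "pressure",
                     "tissue.small_strain_stiffness")
  tissue <- do.call(tissue_preset, targs)
  so <- raw$solver %||% list()
  structure(list(assembly = coated_assembly(probe, coating), tissue = tissue,
                 solver = list(mesh = so$mesh %||% "default",
                               bc = so$bc %||% "fixed_pinned",
                               backend = so$backend %||% "surrogate"),
                 hash = config_hash(raw)),
            class = "pf_config")
}

config_hash <- function(x) {
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  # small deterministic multiplicative hash (no external digest dependency)
  h <- 216613626
  for (ch in utf8ToInt(s)) h <- (bitwXor(as.integer(h), ch) * 69069) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a run record to disk
#'
#' Writes a JSON summary (config hash, package version, forces in mN and SI)
#' plus CSV tables for any force profile; a write-then-read round trip
#' reproduces the numbers exactly.
#'
#' @param record Named list; recognised elements: `prediction`
#'   (`pf_prediction`), `profile` (`pf_force_profile`), plus arbitrary scalar
#'   summaries.
#' @param dir Output directory (created if needed).
#' @param config Optional `pf_config` whose hash is recorded.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(record, dir, config = NULL) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) pf_stop("pf_io_error", "cannot create '%s'", dir)
  paths <- character(0)
  summ <- list(artifact = "probeflex",
               version = as.character(utils::packageVersion("probeflex")),
               timestamp = format(Sys.time(), tz = "UTC"),
               config_hash = if (!is.null(config)) config$hash else NA)
  if (!is.null(record$prediction)) {
    p <- record$prediction
    summ$buckling_force_mN <- mN(p$buckling_force)
    summ$insertion_force_mN <- mN(p$insertion_force)
    summ$buckling_force_N <- p$buckling_force
    summ$insertion_force_N <- p$insertion_force
    summ$safety_factor <- p$safety_factor
  }
  if (!is.null(record$profile)) {
    pr <- record$profile
    csv <- file.path(dir, "force_profile.csv")
    df <- data.frame(displacement_um = m_to_um(pr$samples$displacement_m),
                     force_mN = mN(pr$samples$force_N),
                     side_friction_mN = mN(pr$samples$side_friction_N))
    write.csv(format(df, digits = 17), csv, row.names = FALSE, quote = FALSE)
    paths <- c(paths, csv)
    summ$insertion_force_mN <- mN(pr$insertion_force)
    summ$insertion_force_N <- pr$insertion_force
  }
  extra <- record[setdiff(names(record), c("prediction", "profile"))]
  summ <- c(summ, extra)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, js))
}
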