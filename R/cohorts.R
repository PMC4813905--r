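# Packaged cohort outcome fixtures: probes tested ex vivo in embryonic chick
# brain (15 cohorts) and adult rat brain (7 cohorts), with pass/fail counts.

.cohort_md5 <- c(chick = "1bed909d37840ca056b9fd079575ced8",
                 rat   = "086b2de582104dcb7519fff06117dd7c")

#' Load the packaged cohort outcome fixtures
#'
#' Each record carries the probe/coating geometry, the tissue, and the
#' insertion outcome counts. Success rates are recomputed from the counts and
#' checked against the transcribed percentage column; the fixture file's
#' checksum is verified before parsing.
#'
#' The polymer-shank cohort (rat 7) has no probe dimensions and is treated as
#' coating-only: a probe of negligible stiffness is substituted. Three chick
#' cohorts list coating transverse dimensions smaller than the SU-8 probe they
#' encapsulate; for those rows the transverse numbers are interpreted as
#' per-side layer thicknesses (the coating is applied to each side during
#' fabrication), so the overall coating still encloses the probe.
#'
#' @param table_id `"chick"` or `"rat"`.
#' @param library Material library used to resolve probe materials.
#' @return A list of `pf_cohort` records, each with elements `assembly`,
#'   `tissue_label`, `n_total`, `n_pass`, `success_rate`.
#' @export
load_cohort_fixtures <- function(table_id = c("chick", "rat"),
                                 library = material_library()) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", paste0("cohorts_", table_id, ".csv"),
                      package = "probeflex", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .cohort_md5[[table_id]])
    pf_stop("pf_corrupted_fixture", "fixture %s failed checksum", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  library$shank <- material("shank", 1e3, 1000, 0.45)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (is.na(r$probe_w_um)) {   # coating-only polymer shank
      probe <- probe_spec(1, 1, 3500, library$shank)
    } else {
      probe <- probe_spec(r$probe_w_um, r$probe_t_um, r$probe_L_um,
                          resolve_material(r$probe_material, library))
    }
    coating <- NULL
    if (!is.na(r$coat_t_um)) {
      ct <- r$coat_t_um; cw <- r$coat_w_um
      if (!is.na(r$probe_w_um) &&
          (ct < r$probe_t_um || cw < r$probe_w_um)) {
        ct <- r$probe_t_um + 2 * r$coat_t_um
        cw <- r$probe_w_um + 2 * r$coat_w_um
      }
      coating <- coating_spec(ct, cw, r$coat_L_um)
    }
    rate <- r$n_pass / r$n_total
    if (abs(round(100 * rate, 1) - r$success_rate_pct) > 0.05)
      pf_stop("pf_corrupted_fixture",
              "cohort %s/%s: counts disagree with printed rate", table_id, r$cohort_id)
    structure(list(id = paste0(table_id, "_", r$cohort_id),
                   assembly = coated_assembly(probe, coating),
                   tissue_label = r$tissue,
                   n_total = r$n_total, n_pass = r$n_pass,
                   success_rate = rate),
              class = "pf_cohort")
  })
}

#' All 22 cohorts as a single list
#' @inheritParams load_cohort_fixtures
#' @export
load_all_cohorts <- function(library = material_library()) {
  c(load_cohort_fixtures("chick", library), load_cohort_fixtures("rat", library))
}
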