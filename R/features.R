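#' Assemble the full 288-feature vector for one patient
#'
#' Concatenates 21 dose-volume parameters (from the 3D cumulative surface
#' dose), 43 texture features and 224 dose-geometric parameters (both from
#' the RSDM) in a stable named order.
#'
#' @param cum the patient's `cumulative_surface_dose`.
#' @param map the patient's `rsdm`.
#' @param wall_thickness_mm rectal wall thickness for the DVP area-to-volume
#'   conversion (default 3 mm).
#' @param n_levels texture quantization depth (default 32).
#' @param dgp_levels DGP dose levels (default 45:100 Gy).
#' @param patient_id optional id used in error messages.
#' @return named numeric vector of length 288.
#' @export
assemble_features <- function(cum, map, wall_thickness_mm = 3, n_levels = 32,
                              dgp_levels = 45:100, patient_id = NULL) {
  out <- tryCatch({
    dvp <- compute_dvps(cum$dose, vertex_areas(cum$mesh), wall_thickness_mm)
    attr(dvp, "truncated") <- NULL
    tex <- texture_features(map, n_levels)
    dgp <- compute_dgps(map, dgp_levels)
    c(dvp, tex, dgp)
  }, error = function(e) {
    stopf("feature extraction failed%s: %s",
          if (is.null(patient_id)) "" else sprintf(" for patient %s", patient_id),
          conditionMessage(e))
  })
  out
}

#' Run accumulation, flattening and feature extraction for a whole cohort
#'
#' For each patient the non-reference BT fractions are mapped onto the first
#' fraction either by the package registration (`dvf_method = "cpd"`) or by
#' injecting the generator's stored true correspondences
#' (`dvf_method = "true"`, synthetic patients only), the homogeneous EBRT
#' phase is added, the cumulative dose is flattened, and the 288 features are
#' assembled.
#'
#' @param patients list of `synthetic_patient` objects (see
#'   [generate_cohort]).
#' @param dvf_method `"cpd"` or `"true"`.
#' @param reg_params [register_params] for `dvf_method = "cpd"`.
#' @param params an [eqd2_params].
#' @param wall_thickness_mm,n_levels,dgp_levels passed to
#'   [assemble_features].
#' @return a `feature_table`: list with `features` (patients x 288 matrix),
#'   `labels`, `patient_ids`.
#' @export
cohort_features <- function(patients, dvf_method = c("true", "cpd"),
                            reg_params = register_params(),
                            params = eqd2_params(), wall_thickness_mm = 3,
                            n_levels = 32, dgp_levels = 45:100) {
  dvf_method <- match.arg(dvf_method)
  rows <- vector("list", length(patients))
  for (p in seq_along(patients)) {
    pat <- patients[[p]]
    ref <- pat$fractions[[1]]
    others <- pat$fractions[-1]
    dvfs <- if (dvf_method == "true") {
      pat$true_dvfs[-1]
    } else {
      lapply(others, function(fr) register(fr$mesh, ref$mesh, reg_params))
    }
    cum <- accumulate_bt(ref, others, dvfs, params)
    cum <- add_ebrt(cum, pat$scheme$ebrt_total, pat$scheme$ebrt_d, params)
    map <- flatten(cum, patient_id = pat$id)
    rows[[p]] <- assemble_features(cum, map, wall_thickness_mm, n_levels,
                                   dgp_levels, patient_id = pat$id)
  }
  feats <- do.call(rbind, rows)
  rownames(feats) <- vapply(patients, function(p) as.character(p$id),
                            character(1))
  feature_table(feats,
                labels = vapply(patients, `[[`, integer(1), "label"),
                patient_ids = vapply(patients, `[[`, integer(1), "id"))
}

#' Patients-by-features table with binary toxicity labels
#'
#' @param features numeric matrix, one row per patient, named columns.
#' @param labels binary vector (1 = toxicity).
#' @param patient_ids optional ids.
#' @export
feature_table <- function(features, labels, patient_ids = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stopf("feature table contains missing values")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (length(labels) != nrow(features)) stopf("label length mismatch")
  if (is.null(colnames(features)) ||
      anyDuplicated(colnames(features)) > 0) {
    stopf("features must have unique column names")
  }
  structure(list(features = features, labels = labels,
                 patient_ids = patient_ids %||% seq_len(nrow(features))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features, %d toxicity\n",
              nrow(x$features), ncol(x$features), sum(x$labels)))
  invisible(x)
}

#' Family tag (DVP / texture / DGP) of feature names
#' @param names character vector of feature names.
#' @export
feature_family <- function(names) {
  ifelse(grepl("^D[0-9.]+cc$", names), "DVP",
         ifelse(grepl("^(area|perim|width|length)[0-9]+$", names), "DGP",
                "texture"))
}

#' Write / read a feature table as CSV (patient id, label, 288 columns)
#' @param table a [feature_table].
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(patient = table$patient_ids, label = table$labels,
                   table$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df$patient)
  feature_table(m, df$label, df$patient)
}
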