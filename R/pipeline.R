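#' End-to-end analysis of a multi-patient study
#'
#' Sequences the whole pipeline over a list of patients: voxel-wise
#' IVIM/ADC fitting with QC, VOI summarisation, assembly of the cohort
#' table, group-association statistics, and (when both involvement
#' classes have at least two patients) the stepwise logistic
#' classifier. Every stage's outputs are serialised under `output_dir`
#' with fixed 10-significant-digit formatting, so reruns with the same
#' inputs diff clean. Progress and invalid-voxel counts go to
#' `message()` (stderr).
#'
#' @param patients A list; each element a list with `id`, `study`
#'   ([dwi_study]), `voi` ([tumour_voi]) and `group` (one of `"none"`,
#'   `"sub_centimetre"`, `"size_significant"`). A missing `voi` aborts
#'   naming the patient.
#' @param output_dir Directory for outputs (created if needed).
#' @param config A [fit_config].
#' @param candidates Candidate features for the classifier.
#' @param write_nifti Also write each patient's parametric maps as
#'   NIfTI files (default FALSE; summaries and statistics are always
#'   written).
#' @return Invisibly, a list with `cohort` (data frame), `stats`,
#'   `classifier` (or NULL), `score` (or NULL) and the output paths.
#' @export
run_pipeline <- function(patients, output_dir, config = fit_config(),
                         candidates = c("dtv", "adc", "d", "f"),
                         write_nifti = FALSE) {
  if (!length(patients)) stop("no patients supplied", call. = FALSE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  groups <- c("none", "sub_centimetre", "size_significant")

  rows <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    id <- if (!is.null(p$id)) p$id else i
    for (need in c("study", "voi", "group"))
      if (is.null(p[[need]]))
        stop(sprintf("patient %s: missing %s", id, need), call. = FALSE)
    message(sprintf("[fit] patient %s", id))
    maps <- fit_ivim(p$study, config)
    message(sprintf("[fit] patient %s: %d/%d voxels valid after QC",
                    id, sum(maps$valid), length(maps$valid)))
    if (write_nifti)
      write_maps(maps, file.path(output_dir, paste0("maps_", id)))
    sm <- summarize_voi(maps, p$voi)
    row <- as.data.frame(sm)
    # cohort table carries ADC and D in the display unit 1e-3 mm^2/s
    row$adc <- row$adc_mean * 1e3
    row$d <- row$d_mean * 1e3
    row$f <- row$f_mean
    rows[[i]] <- cbind(data.frame(id = id, group = factor(p$group, levels = groups)),
                       row)
  }
  cohort <- do.call(rbind, rows)
  cohort$involved <- as.integer(cohort$group != "none")
  write_fixed_csv(cohort, file.path(output_dir, "cohort.csv"))

  message("[stats] group associations")
  stats_tab <- cohort_association_stats(cohort)
  write_fixed_csv(stats_tab, file.path(output_dir, "stats.csv"))

  clf <- score <- NULL
  tab <- table(cohort$involved)
  if (length(tab) == 2L && min(tab) >= 2L) {
    message("[classify] stepwise logistic model")
    clf <- pln_classifier(cohort, candidates = candidates)
    score <- score_classifier(clf)
    report <- list(selected = clf$selected,
                   coefficients = as.list(clf$coefficients),
                   separable = clf$separable,
                   accuracy = score$accuracy$estimate,
                   sensitivity = score$sensitivity$estimate,
                   specificity = score$specificity$estimate,
                   auc = score$auc,
                   predictions = data.frame(id = cohort$id,
                                            prob = round(score$prob, 10),
                                            predicted = score$predicted,
                                            truth = score$truth))
    jsonlite::write_json(report, file.path(output_dir, "classifier.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  } else {
    message("[classify] skipped: need >= 2 patients in each involvement class")
  }

  invisible(list(cohort = cohort, stats = stats_tab,
                 classifier = clf, score = score, output_dir = output_dir))
}

# CSVs with a fixed decimal format so byte-identical reruns diff clean
write_fixed_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
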