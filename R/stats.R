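#' One-way ANOVA F-statistic
#'
#' Between-group over within-group variance ratio:
#' `F = [sum n_k (xbar_k - xbar)^2 / (K - 1)] / [sum_k sum_i (x_ki -
#' xbar_k)^2 / (N - K)]`, with the upper-tail p-value from the F
#' distribution on `(K - 1, N - K)` degrees of freedom. Zero within-group
#' variance with unequal means yields `F = Inf`, `p = 0`.
#'
#' @param values numeric observations.
#' @param labels group labels (two or more classes, >= 2 observations each).
#' @return named vector `c(F =, p =)`.
#' @export
anova_f <- function(values, labels) {
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  ok <- is.finite(values)
  values <- values[ok]; labels <- as.character(labels)[ok]
  groups <- split(values, labels)
  if (length(groups) < 2) stop("need at least two classes")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every class needs at least 2 observations")
  n_k <- vapply(groups, length, numeric(1))
  m_k <- vapply(groups, mean, numeric(1))
  N <- sum(n_k); K <- length(groups)
  gm <- sum(n_k * m_k) / N
  ssb <- sum(n_k * (m_k - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    if (ssb == 0) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  f <- (ssb / (K - 1)) / (ssw / (N - K))
  c(F = f, p = stats::pf(f, K - 1, N - K, lower.tail = FALSE))
}

# Canonical feature order and display names of the separability report.
FEATURE_ORDER <- data.frame(
  category = c(rep("Shape", 4), rep("First-order", 7), rep("GLCM", 9),
               rep("NGTDM", 5)),
  name = c("Solidity", "Sphericity", "Elongation", "Flatness",
           "Mean", "Median", "Variance", "Entropy", "Skewness", "Kurtosis",
           "Uniformity",
           "Autocorrelation", "Contrast", "Correlation", "Difference Average",
           "Inverse Difference", "Joint Average", "Joint Energy",
           "Joint Entropy", "Sum of Squares",
           "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
  column = c("shape_solidity", "shape_sphericity", "shape_elongation",
             "shape_flatness", "firstorder_mean", "firstorder_median",
             "firstorder_variance", "firstorder_entropy",
             "firstorder_skewness", "firstorder_kurtosis",
             "firstorder_uniformity", "glcm_autocorrelation",
             "glcm_contrast", "glcm_correlation", "glcm_difference_average",
             "glcm_inverse_difference", "glcm_joint_average",
             "glcm_joint_energy", "glcm_joint_entropy", "glcm_sum_of_squares",
             "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
             "ngtdm_complexity", "ngtdm_strength"),
  stringsAsFactors = FALSE)

#' Per-feature class-separability table
#'
#' One-way ANOVA separability score (F) and p-value per radiomic feature
#' between two lesion classes, in the canonical 25-feature order. Rows with
#' missing feature values are flagged, not dropped.
#'
#' @param tab a [feature_table()] data frame.
#' @param class_column column holding the class assignment
#'   (default `"class"`).
#' @param classes the two class labels to compare (default
#'   `c("malignant", "benign")`).
#' @param n_levels bin-number metadata recorded with the table.
#' @return data frame: `category`, `name`, `F`, `p`, `flagged`; attribute
#'   `"fixed_bin_number"`.
#' @export
separability_table <- function(tab, class_column = "class",
                               classes = c("malignant", "benign"),
                               n_levels = 64L) {
  sel <- tab[[class_column]] %in% classes
  sub <- tab[sel, , drop = FALSE]
  rows <- lapply(seq_len(nrow(FEATURE_ORDER)), function(i) {
    col <- FEATURE_ORDER$column[i]
    vals <- sub[[col]]
    flagged <- any(!is.finite(vals))
    ok <- is.finite(vals)
    fp <- if (sum(ok) >= 4 &&
              all(table(sub[[class_column]][ok]) >= 2))
      anova_f(vals[ok], sub[[class_column]][ok])
    else c(F = NA_real_, p = NA_real_)
    data.frame(category = FEATURE_ORDER$category[i],
               name = FEATURE_ORDER$name[i], F = fp[["F"]], p = fp[["p"]],
               flagged = flagged)
  })
  out <- do.call(rbind, rows)
  attr(out, "fixed_bin_number") <- n_levels
  out
}

#' Write the separability report as delimited text
#'
#' p-values are displayed to 3 decimals (floored at 0); full precision stays
#' in the returned data frame.
#'
#' @param sep_tab a [separability_table()].
#' @param path output path (CSV).
#' @export
write_separability_table <- function(sep_tab, path) {
  out <- sep_tab
  out$p <- sprintf("%.3f", round(out$p, 3))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Retain unspecified findings of benchmark intensity
#'
#' Keeps the unspecified ROIs of a patient whose mean intensity is
#' comparable to or above the patient's detected index-lesion ROI:
#' `mean(ROI) >= kappa * mean(index)`. Patients without a detected index
#' lesion are excluded from the false-positive analysis.
#'
#' @param unspecified list of ROI records (label `UNSPECIFIED`).
#' @param index_roi the patient's dominant detected lesion ROI, or `NULL`.
#' @param kappa comparability factor (default 0.9; 0 disables the filter).
#' @return the retained subset (empty when `index_roi` is `NULL`).
#' @export
benchmark_intensity <- function(unspecified, index_roi, kappa = 0.9) {
  if (is.null(index_roi)) return(list())
  ref <- index_roi$mean
  Filter(function(r) r$mean >= kappa * ref, unspecified)
}

#' False-positive rate from analysis counts
#'
#' `fp_rate = 100 * n_confused / n_healthy_breasts` (percent).
#'
#' @param n_confused unspecified findings confused with malignant lesions.
#' @param n_healthy healthy breasts in the analysis.
#' @export
fp_rate <- function(n_confused, n_healthy) {
  if (n_healthy <= 0) stop("report error: no healthy breasts in input")
  100 * n_confused / n_healthy
}

#' False-positive workflow over unspecified findings
#'
#' Places malignant and benign class centroids in a standardized feature
#' subspace (default: first-order entropy, GLCM joint entropy, NGTDM
#' strength -- the most discriminative feature triplet), assigns each
#' retained unspecified finding to the nearer centroid, counts the findings
#' confused with the malignant class, and reports the false-positive rate
#' per healthy breast. Standardization (mean/sd) is fitted on the labelled
#' lesion rows only, before classifying the unspecified findings.
#'
#' @param tab a [feature_table()] data frame containing labelled lesions
#'   (`class` in `classes`) and retained unspecified findings (`label ==
#'   "UNSPECIFIED"`).
#' @param n_healthy number of healthy breasts in the analysis set.
#' @param features feature columns of the classification subspace.
#' @param classes `c(malignant_label, benign_label)`.
#' @return object of class `fp_report`: counts, rate and per-finding
#'   provenance.
#' @export
fp_workflow <- function(tab, n_healthy,
                        features = c("firstorder_entropy",
                                     "glcm_joint_entropy",
                                     "ngtdm_strength"),
                        classes = c("malignant", "benign")) {
  if (n_healthy <= 0) stop("report error: no healthy breasts in input")
  les <- tab[tab$class %in% classes & !is.na(tab$class), , drop = FALSE]
  uns <- tab[tab$label == "UNSPECIFIED", , drop = FALSE]
  if (nrow(les) < 2 || !all(classes %in% les$class))
    stop("need labelled lesions of both classes to place centroids")
  X <- as.matrix(les[, features, drop = FALSE])
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  std <- function(M) sweep(sweep(M, 2, mu), 2, sg, `/`)
  Xs <- std(X)
  cen <- rbind(colMeans(Xs[les$class == classes[1], , drop = FALSE]),
               colMeans(Xs[les$class == classes[2], , drop = FALSE]))
  n_uns <- nrow(uns)
  confused <- logical(0)
  prov <- NULL
  if (n_uns > 0) {
    U <- std(as.matrix(uns[, features, drop = FALSE]))
    d1 <- sqrt(rowSums(sweep(U, 2, cen[1, ])^2))
    d2 <- sqrt(rowSums(sweep(U, 2, cen[2, ])^2))
    confused <- d1 < d2
    prov <- data.frame(breast_id = uns$breast_id,
                       d_malignant = d1, d_benign = d2,
                       confused = confused)
  }
  structure(list(n_healthy_breasts = n_healthy, n_unspecified = n_uns,
                 n_confused = sum(confused),
                 fp_rate = fp_rate(sum(confused), n_healthy),
                 features = features, findings = prov),
            class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf(paste0("<fp_report> %d unspecified finding(s) in %d healthy ",
                     "breast(s); %d confused with malignant -> FP rate %.1f%%\n"),
              x$n_unspecified, x$n_healthy_breasts, x$n_confused, x$fp_rate))
  invisible(x)
}
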