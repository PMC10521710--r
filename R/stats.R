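# Blinded-study arithmetic: ROI sampling, confusion matrices, agreement
# tests and paired quality-score t-tests.

#' Read HER2 score records (long-form CSV)
#'
#' Whole-slide scoring tables have columns `wsi_id`, `patient_id`,
#' `modality` ("virtual" or "ihc"), `reader_id`, `assigned`, `reference`
#' (HER2 labels "0", "1+", "2+", "3+"). Quality tables have `roi_id`,
#' `modality`, `reader_id`, `metric`, `grade` (1-4; empty grade = not
#' applicable, e.g. membrane clearness on HER2-negative ROIs).
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_score_records <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("wsi_id", "patient_id", "modality", "reader_id", "assigned",
            "reference")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  if (!all(d$modality %in% c("virtual", "ihc")))
    stop("modality must be 'virtual' or 'ihc'")
  her2_score(d$assigned); her2_score(d$reference)  # validate labels
  if (anyDuplicated(d[c("wsi_id", "reader_id", "modality")]))
    stop("duplicate (wsi, reader, modality) records")
  d
}

#' @rdname read_score_records
#' @export
read_quality_records <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "modality", "reader_id", "metric", "grade")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  ok <- is.na(d$grade) | d$grade %in% 1:4
  if (!all(ok)) stop("grades must be 1..4 or missing")
  d
}

#' Sample co-located regions of interest from paired WSIs
#'
#' Draws `n_per_wsi` seeded ROI origins per slide, identical in the virtual
#' and the IHC member, keeping only origins whose ROI contains at least
#' `min_tissue_frac` tissue (luminance < 0.95 in the IHC member).
#'
#' @param wsis list of paired slides, each a list with `id`, `virtual` and
#'   `ihc` (`[H, W, 3]` arrays).
#' @param n_per_wsi ROIs per slide (10 in the blinded study).
#' @param roi_size ROI side in pixels (8000 at full scale).
#' @param seed integer seed.
#' @param min_tissue_frac minimum tissue fraction per ROI.
#' @return data.frame of class `roi_set` (wsi_id, roi_id, row, col) with the
#'   extracted patches in attribute `patches` (named list with `virtual` and
#'   `ihc` members per ROI); `n_patches` attribute counts both modalities.
#' @export
sample_rois <- function(wsis, n_per_wsi = 10L, roi_size = 8000L, seed = 0L,
                        min_tissue_frac = 0.05) {
  recs <- NULL; patches <- list()
  with_seed(seed, {
    for (w in wsis) {
      d <- dim(w$virtual)
      if (roi_size > d[1] || roi_size > d[2])
        stop("WSI smaller than roi_size")
      tiss <- luminance(w$ihc) < 0.95
      got <- 0L; tries <- 0L
      while (got < n_per_wsi && tries < 200L * n_per_wsi) {
        tries <- tries + 1L
        r0 <- sample.int(d[1] - roi_size + 1L, 1L) - 1L
        c0 <- sample.int(d[2] - roi_size + 1L, 1L) - 1L
        rows <- (r0 + 1L):(r0 + roi_size); cols <- (c0 + 1L):(c0 + roi_size)
        if (mean(tiss[rows, cols]) < min_tissue_frac) next
        got <- got + 1L
        roi_id <- sprintf("%s_roi%02d", w$id, got)
        recs <- rbind(recs, data.frame(wsi_id = w$id, roi_id = roi_id,
                                       row = r0, col = c0))
        patches[[roi_id]] <- list(
          virtual = w$virtual[rows, cols, , drop = FALSE],
          ihc = w$ihc[rows, cols, , drop = FALSE])
      }
      if (got < n_per_wsi)
        stop("could not place ", n_per_wsi, " tissue ROIs in ", w$id)
    }
  })
  attr(recs, "patches") <- patches
  attr(recs, "n_patches") <- 2L * nrow(recs)
  class(recs) <- c("roi_set", class(recs))
  recs
}

#' Build a 4x4 HER2 confusion matrix
#'
#' Rows are the assigned (pathologist) scores, columns the reference
#' (ground-truth) scores.
#' @param records score records (see [read_score_records()]).
#' @param modality "virtual" or "ihc".
#' @return Integer 4x4 matrix of class `confusion_matrix4`.
#' @export
build_confusion <- function(records, modality = c("virtual", "ihc")) {
  modality <- match.arg(modality)
  r <- records[records$modality == modality, ]
  if (!nrow(r)) stop("no records for modality ", modality)
  lv <- her2_levels()
  m <- table(factor(as.character(r$assigned), levels = lv),
             factor(as.character(r$reference), levels = lv))
  m <- matrix(as.integer(m), 4, 4, dimnames = list(assigned = lv,
                                                   reference = lv))
  class(m) <- c("confusion_matrix4", class(m))
  m
}

#' Diagonal sum and weighted off-diagonal error of a confusion matrix
#'
#' The diagonal sum counts correctly scored slides; the weighted
#' off-diagonal error is `sum over i != j of counts[i, j] * |i - j|` with
#' scores coded 0..3, i.e. each mis-scoring weighted by how many HER2
#' levels it misses by.
#' @param m a `confusion_matrix4`.
#' @return Named vector `c(diag_sum, weighted_offdiag_error)`.
#' @export
confusion_summaries <- function(m) {
  stopifnot(all(dim(m) == c(4L, 4L)))
  idx <- abs(outer(0:3, 0:3, `-`))
  c(diag_sum = sum(diag(m)),
    weighted_offdiag_error = sum(m * idx))
}

#' Pearson chi-square test on a contingency table
#'
#' Plain two-sided Pearson test, `sum (O - E)^2 / E`, no continuity
#' correction; warns when any expected count falls below 5.
#' @param tab contingency table (matrix of counts).
#' @return List of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `expected`.
#' @export
chi_square_test <- function(tab) {
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    message("dropping zero-margin rows/columns from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected counts below 5; chi-square approximation is coarse")
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), expected = ct$expected),
            class = "chisq_result")
}

#' Chi-square comparison of scoring agreement between modalities
#'
#' Builds a modality-by-category contingency table from the two confusion
#' matrices and applies the two-sided Pearson chi-square test.  The layout
#' is a policy: `"correct_total"` (default) tabulates correct vs incorrect
#' assignments per modality; `"assigned_margin"` tabulates the distribution
#' of assigned scores per modality.
#'
#' @param virtual_m,ihc_m `confusion_matrix4` objects with equal totals.
#' @param layout contingency construction policy.
#' @return A `chisq_result` (see [chi_square_test()]) with the table in
#'   `$table`.
#' @export
chi_square_agreement <- function(virtual_m, ihc_m,
                                 layout = c("correct_total",
                                            "assigned_margin")) {
  layout <- match.arg(layout)
  if (sum(virtual_m) != sum(ihc_m))
    stop("matrices must aggregate the same number of evaluations")
  tab <- switch(layout,
    correct_total = rbind(
      virtual = c(correct = sum(diag(virtual_m)),
                  incorrect = sum(virtual_m) - sum(diag(virtual_m))),
      ihc = c(correct = sum(diag(ihc_m)),
              incorrect = sum(ihc_m) - sum(diag(ihc_m)))),
    assigned_margin = rbind(virtual = rowSums(virtual_m),
                            ihc = rowSums(ihc_m)))
  out <- chi_square_test(tab)
  out$table <- tab
  out
}

#' One-sided paired t-test on staining quality scores
#'
#' For one feature metric and one reader, pairs each ROI's virtual and IHC
#' quality grades, forms differences `d = virtual - IHC`, and tests whether
#' the IHC staining scores higher (alternative: mean d < 0). Pairs with a
#' missing member (e.g. membrane clearness on HER2-negative ROIs) are
#' dropped. If all differences are zero the test is uninformative and
#' p = 0.5 by convention; constant nonzero differences give the degenerate
#' limit p = 0 (mean d < 0) or p = 1 (mean d > 0).
#'
#' @param records quality records (see [read_quality_records()]).
#' @param metric feature metric name.
#' @param reader_id reader identifier.
#' @return List of class `ttest_result`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `n`, `direction`.
#' @export
paired_quality_ttest <- function(records, metric, reader_id) {
  r <- records[records$metric == metric & records$reader_id == reader_id, ]
  v <- r[r$modality == "virtual", c("roi_id", "grade")]
  i <- r[r$modality == "ihc", c("roi_id", "grade")]
  m <- merge(v, i, by = "roi_id", suffixes = c("_v", "_i"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 2L) stop("fewer than 2 complete pairs")
  d <- m$grade_v - m$grade_i
  n <- length(d)
  if (sd(d) == 0) {
    p <- if (mean(d) == 0) 0.5 else if (mean(d) < 0) 0 else 1
    t_ <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_ <- mean(d) / (sd(d) / sqrt(n))
    p <- pt(t_, df = n - 1)           # lower tail: alternative mean d < 0
  }
  structure(list(statistic = t_, df = n - 1L, p_value = p,
                 mean_difference = mean(d), n = n,
                 direction = "IHC better than virtual (mean d < 0)"),
            class = "ttest_result")
}
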