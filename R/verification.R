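# Verification scoring: success rate over subject pairs, and false
# acceptance / false rejection at a tuned threshold.

#' Success rate from a pairwise group-distance matrix
#'
#' A subject should be closer to itself than to anyone else.  For every
#' ordered pair (L, K), L != K, an identification error is counted when the
#' inter-group distance `mat[L, K]` is less than or equal to the baseline
#' intra-group distance (the row subject's diagonal entry by default).
#' Boundary equality counts as an error.  The success rate is
#' `1 - errors / (n * (n - 1))`.
#'
#' @param mat square numeric matrix with intra-group distances on the
#'   diagonal (e.g. from [pairwise_matrix]).
#' @param baseline which diagonal entry an off-diagonal entry is compared
#'   against: the row subject's (`"row"`, default), the column subject's
#'   (`"column"`), or an error when below either (`"both"`).
#' @return list with `errors`, `total_comparisons` and `rate`.
#' @export
success_rate <- function(mat, baseline = c("row", "column", "both")) {
  baseline <- match.arg(baseline)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    abort("matrix not square: got %d x %d", NROW(mat), NCOL(mat))
  }
  n <- nrow(mat)
  total <- n * (n - 1L)
  if (total == 0L) {
    return(list(errors = 0L, total_comparisons = 0L, rate = NA_real_))
  }
  d <- diag(mat)
  # err_row[i, j]: mat[i, j] <= diag[i] (diag recycles down rows)
  err_row <- mat <= d
  err_col <- t(t(mat) <= d)
  err <- switch(baseline,
                row = err_row,
                column = err_col,
                both = err_row | err_col)
  diag(err) <- FALSE
  errors <- sum(err)
  list(errors = errors, total_comparisons = total,
       rate = 1 - errors / total)
}

#' False acceptance and false rejection at a threshold
#'
#' A comparison is accepted when its distance is less than or equal to the
#' threshold.  FR is the fraction of genuine (same-subject) distances
#' rejected; FA is the fraction of impostor (cross-subject) distances
#' accepted.
#'
#' @param genuine numeric vector of same-subject distances.
#' @param impostor numeric vector of cross-subject distances.
#' @param threshold acceptance threshold.
#' @return list with `fa` and `fr`.
#' @export
fa_fr <- function(genuine, impostor, threshold) {
  if (length(genuine) == 0L || length(impostor) == 0L) {
    abort("no scores: genuine and impostor lists must be non-empty")
  }
  list(fa = mean(impostor <= threshold), fr = mean(genuine > threshold))
}

#' Tune the acceptance threshold to minimize (FA + FR) / 2
#'
#' Scans all midpoints between adjacent values of the pooled sorted score
#' list, plus a reject-all and an accept-all extreme, and returns the
#' threshold minimizing `(FA + FR) / 2`; ties are broken toward the
#' smaller threshold.
#'
#' @inheritParams fa_fr
#' @return list with `threshold`, `fa`, `fr` and `objective`.
#' @export
tune_threshold <- function(genuine, impostor) {
  if (length(genuine) == 0L || length(impostor) == 0L) {
    abort("no scores: genuine and impostor lists must be non-empty")
  }
  v <- sort(unique(c(genuine, impostor)))
  cands <-
    if (length(v) == 1L) c(v - 1, v)
    else c(v[1L] - 1, (v[-length(v)] + v[-1L]) / 2, v[length(v)])
  obj <- vapply(cands, function(th) {
    r <- fa_fr(genuine, impostor, th)
    (r$fa + r$fr) / 2
  }, numeric(1))
  best <- which.min(obj)  # first minimum = smallest threshold
  r <- fa_fr(genuine, impostor, cands[best])
  list(threshold = cands[best], fa = r$fa, fr = r$fr, objective = obj[best])
}

#' End-to-end verification report over segment sets
#'
#' Builds the pairwise group-distance matrix over the given subjects'
#' segment sets, scores the success rate, and tunes an acceptance
#' threshold taking the diagonal (intra-group) distances as genuine scores
#' and the off-diagonal (inter-group) distances as impostor scores.
#'
#' @param sets list of `segment_set` objects, one per subject.
#' @param params an [rbp_params].
#' @param baseline passed to [success_rate].
#' @return an object of class `verification_report`: list with
#'   `success_rate`, `total_errors`, `total_comparisons`, `fa`, `fr`,
#'   `threshold` and `per_pair` (the distance matrix).
#' @export
evaluate_verification <- function(sets, params = rbp_params(),
                                  baseline = "row") {
  mat <- pairwise_matrix(sets, params)
  sr <- success_rate(mat, baseline)
  if (nrow(mat) > 1L) {
    genuine <- diag(mat)
    impostor <- mat[row(mat) != col(mat)]
    tt <- tune_threshold(genuine, impostor)
  } else {
    tt <- list(threshold = NA_real_, fa = NA_real_, fr = NA_real_)
  }
  structure(list(success_rate = sr$rate, total_errors = sr$errors,
                 total_comparisons = sr$total_comparisons,
                 fa = tt$fa, fr = tt$fr, threshold = tt$threshold,
                 per_pair = mat),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %d subjects\n", nrow(x$per_pair)))
  cat(sprintf("  success rate: %.3f (%d errors / %d comparisons)\n",
              x$success_rate, x$total_errors, x$total_comparisons))
  cat(sprintf("  FA %.4f / FR %.4f at threshold %.4f\n",
              x$fa, x$fr, x$threshold))
  invisible(x)
}

#' Serialize a verification report to JSON
#'
#' @param report a `verification_report`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "verification_report"))
  obj <- list(success_rate = report$success_rate,
              total_errors = report$total_errors,
              total_comparisons = report$total_comparisons,
              fa = report$fa, fr = report$fr, threshold = report$threshold,
              subjects = rownames(report$per_pair),
              per_pair = unname(apply(report$per_pair, 1, as.numeric,
                                      simplify = FALSE)))
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
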