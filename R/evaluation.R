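# Accuracy metrics and reports: per-axis translational errors, Euclidean
# distance (ED), geodesic angular error (GA), the 10 mm success rule,
# landmark target registration error (TRE), and error ECDF tables.

#' Pose error between an estimated and a ground-truth correction
#'
#' Errors are computed on the left residual `gt^-1 o est`, so they are
#' exactly invariant to pre-composing both poses with a common transform.
#' The residual translation equals `R_gt^T (t_est - t_gt)`; its norm (ED) is
#' therefore `||t_est - t_gt||`. Per-axis translational and rotational
#' components are reported as absolute values; the rotational decomposition
#' uses the package's intrinsic x->y->z Euler convention. A pair is labeled
#' successful when ED is strictly below 10 mm.
#'
#' @param est,gt `rigid_transform` objects with the same center convention.
#' @return one-row `data.frame` with columns `tx, ty, tz, ed` (mm),
#'   `rx, ry, rz, ga` (degrees) and `success` (logical).
#' @export
pose_error <- function(est, gt) {
  stopifnot(inherits(est, "rigid_transform"), inherits(gt, "rigid_transform"))
  if (max(abs(est$center - gt$center)) > 1e-9) {
    stop("pose_error requires a common center convention")
  }
  res <- compose(invert(gt), est)
  tr <- res$translation
  ed <- sqrt(sum(tr^2))
  eul <- rot_to_euler(res$rotation)
  ga <- geodesic_error(res$rotation, diag(3))
  data.frame(tx = abs(tr[1]), ty = abs(tr[2]), tz = abs(tr[3]), ed = ed,
             rx = abs(eul[["rx"]]), ry = abs(eul[["ry"]]), rz = abs(eul[["rz"]]),
             ga = ga, success = ed < 10)
}

#' Landmark set
#'
#' @param points n x 3 matrix of landmark coordinates (mm, center-relative).
#' @param ids landmark identifiers (default `1:n`).
#' @param frame optional frame label.
#' @return list of class `landmark_set`.
#' @export
landmark_set <- function(points, ids = NULL, frame = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1 || !all(is.finite(points))) {
    stop("landmark_set needs at least one finite point")
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))
  stopifnot(length(ids) == nrow(points))
  structure(list(points = points, ids = as.character(ids), frame = frame),
            class = "landmark_set")
}

#' Target registration error on landmarks
#'
#' Mean Euclidean distance between the `T`-mapped moving landmarks and the
#' matched fixed landmarks.
#'
#' @param moving,fixed `landmark_set`s of equal cardinality with matching
#'   identifiers.
#' @param T a `rigid_transform` applied to the moving points.
#' @return list with `mean`, `sd` (sample sd, `NA` for a single landmark)
#'   and `per_landmark` (named distances, mm).
#' @export
tre <- function(moving, fixed, T = identity_transform()) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  if (length(moving$ids) != length(fixed$ids)) stop("landmark sets differ in size")
  ord <- match(moving$ids, fixed$ids)
  if (anyNA(ord)) stop("landmark identifiers do not match")
  mapped <- apply_transform(T, moving$points)
  d <- sqrt(rowSums((mapped - fixed$points[ord, , drop = FALSE])^2))
  names(d) <- moving$ids
  list(mean = mean(d), sd = if (length(d) > 1) sd(d) else NA_real_,
       per_landmark = d)
}

#' Empirical CDF of registration errors
#'
#' Right-continuous ECDF `P(error <= threshold)` evaluated on a threshold
#' grid; monotone nondecreasing and 1.0 at (and beyond) the maximum error.
#'
#' @param errors numeric vector of errors (mm), nonempty.
#' @param thresholds evaluation grid; default 101 points from 0 to the
#'   maximum error.
#' @return `data.frame` with columns `threshold`, `fraction`.
#' @export
error_ecdf <- function(errors, thresholds = NULL) {
  stopifnot(length(errors) > 0, all(is.finite(errors)))
  if (is.null(thresholds)) thresholds <- seq(0, max(errors), length.out = 101)
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(thr) mean(errors <= thr),
                               numeric(1)))
}

#' Summarize a set of pose errors
#'
#' Aggregates rows produced by [pose_error()]: per-axis means, ED/GA mean
#' and sample (n-1) standard deviation, and the success count under the
#' strict 10 mm rule.
#'
#' @param results `data.frame` of pose errors (rows from [pose_error()],
#'   e.g. via `do.call(rbind, ...)`), or a list of such rows.
#' @return list of class `pose_error_summary` with fields `table` (one-row
#'   `data.frame`), `n`, `n_success`, `success_label` (e.g. `"49/50"`).
#' @export
summarize_errors <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  tab <- data.frame(
    tx = mean(results$tx), ty = mean(results$ty), tz = mean(results$tz),
    ed_mean = mean(results$ed),
    ed_sd = if (nrow(results) > 1) sd(results$ed) else NA_real_,
    rx = mean(results$rx), ry = mean(results$ry), rz = mean(results$rz),
    ga_mean = mean(results$ga),
    ga_sd = if (nrow(results) > 1) sd(results$ga) else NA_real_)
  n <- nrow(results)
  k <- sum(results$success)
  structure(list(table = tab, n = n, n_success = k,
                 success_label = sprintf("%d/%d", k, n)),
            class = "pose_error_summary")
}

#' @export
print.pose_error_summary <- function(x, ...) {
  cat("Pose error over", x$n, "pairs (sample sd):\n")
  t <- x$table
  cat(sprintf("  Tx %.2f  Ty %.2f  Tz %.2f  ED %.2f +/- %.2f mm\n",
              t$tx, t$ty, t$tz, t$ed_mean, t$ed_sd))
  cat(sprintf("  Rx %.2f  Ry %.2f  Rz %.2f  GA %.2f +/- %.2f deg\n",
              t$rx, t$ry, t$rz, t$ga_mean, t$ga_sd))
  cat("  successful pairs (ED < 10 mm):", x$success_label, "\n")
  invisible(x)
}

#' Write a pose-error summary to CSV
#' @param x a `pose_error_summary`.
#' @param path output CSV path.
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "pose_error_summary"))
  out <- cbind(x$table, n = x$n, n_success = x$n_success)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
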