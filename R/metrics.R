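# Evaluation and reliability statistics: Spearman's rank correlation, RMSE,
# and the intraclass correlation coefficient under the two-way mixed-effects
# model with absolute agreement (McGraw-Wong ICC(A,1) / ICC(A,k)).

#' Spearman's rank correlation
#'
#' Rank correlation with mid-rank tie handling; invariant under strictly
#' monotone transforms of either argument. Errors (rather than returning NA)
#' on constant input, where the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return correlation in [-1, 1].
#' @export
spearman <- function(x, y) {
  ps_validate(length(x) == length(y), "x and y must have equal length")
  ps_validate(length(x) >= 3L, "need at least 3 observations")
  ps_validate(all(is.finite(x)) && all(is.finite(y)),
              "inputs must be finite")
  ps_validate(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Root mean squared error
#'
#' @param pred,ref numeric vectors of equal non-zero length.
#' @return \code{sqrt(mean((pred - ref)^2))}.
#' @export
rmse <- function(pred, ref) {
  ps_validate(length(pred) == length(ref), "pred and ref must have equal length")
  ps_validate(length(pred) > 0L, "empty input")
  sqrt(mean((pred - ref)^2))
}

#' Ratings matrix constructor
#'
#' Subjects x judges matrix of perceptual scores on the 0-10 scale; complete
#' (no missing cells), at least 2 subjects and 2 judges.
#'
#' @param values numeric matrix, rows = subjects, columns = judges.
#' @param subjects,judges optional identifiers (defaults from dimnames).
#' @return matrix of class \code{ratings_matrix}.
#' @export
ratings_matrix <- function(values, subjects = rownames(values),
                           judges = colnames(values)) {
  values <- as.matrix(values)
  ps_validate(nrow(values) >= 2L && ncol(values) >= 2L,
              "need at least 2 subjects and 2 judges")
  ps_validate(all(is.finite(values)), "ratings must be complete and finite")
  ps_validate(all(values >= 0 & values <= 10),
              "ratings must lie on the 0-10 scale")
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(judges)) judges <- sprintf("J%d", seq_len(ncol(values)))
  dimnames(values) <- list(subjects, judges)
  class(values) <- c("ratings_matrix", "matrix", "array")
  values
}

#' Intraclass correlation, two-way mixed effects, absolute agreement
#'
#' Computed from the two-way ANOVA mean squares (subjects MSR, judges MSC,
#' error MSE). The \code{single} form ICC(A,1) is the reliability of one
#' judge; the \code{average} form ICC(A,k) is the reliability of the k-judge
#' mean, the panel-level default. Absolute agreement penalizes systematic
#' judge bias, so a constant offset between otherwise identical judges lowers
#' the coefficient. Negative ANOVA estimates are reported as computed unless
#' \code{floor_negative}.
#'
#' @param r a \code{\link{ratings_matrix}} (or plain complete matrix).
#' @param form \code{"average"} (default) or \code{"single"}.
#' @param floor_negative floor negative estimates at 0.
#' @return ICC value (at most 1).
#' @export
icc_absolute_agreement <- function(r, form = c("average", "single"),
                                   floor_negative = FALSE) {
  form <- match.arg(form)
  r <- as.matrix(r)
  ps_validate(nrow(r) >= 2L && ncol(r) >= 2L,
              "need at least 2 subjects and 2 judges")
  ps_validate(all(is.finite(r)), "ratings must be complete and finite")
  n <- nrow(r); k <- ncol(r)
  gm <- mean(r)
  row_m <- rowMeans(r); col_m <- colMeans(r)
  msr <- k * sum((row_m - gm)^2) / (n - 1)                 # subjects
  msc <- n * sum((col_m - gm)^2) / (k - 1)                 # judges
  sse <- sum((r - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))

  num <- msr - mse
  icc <- if (form == "single") {
    num / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    num / (msr + (msc - mse) / n)
  }
  if (!is.finite(icc)) {
    ps_stop("ICC undefined: no between-subject variance", "ps_validation_error")
  }
  if (floor_negative) icc <- max(0, icc)
  icc
}

#' Evaluate predictions against reference scores
#'
#' Matches predictions and references on their shared speaker ids and
#' reports Spearman's correlation and RMSE for both tasks.
#'
#' @param predictions,references data.frames with columns \code{id},
#'   \code{int}, \code{sev}; id sets must intersect on at least 3 speakers.
#' @return list of class \code{eval_report}: \code{spearman_int},
#'   \code{spearman_sev}, \code{rmse_int}, \code{rmse_sev}, \code{n}.
#' @export
evaluate <- function(predictions, references) {
  p <- as.data.frame(predictions); r <- as.data.frame(references)
  ps_validate(all(c("id", "int", "sev") %in% names(p)) &&
                all(c("id", "int", "sev") %in% names(r)),
              "inputs need columns id, int, sev")
  ids <- intersect(p$id, r$id)
  ps_validate(length(ids) >= 3L,
              "prediction and reference ids must share at least 3 speakers")
  p <- p[match(ids, p$id), ]
  r <- r[match(ids, r$id), ]
  structure(list(
    spearman_int = spearman(p$int, r$int),
    spearman_sev = spearman(p$sev, r$sev),
    rmse_int = rmse(p$int, r$int),
    rmse_sev = rmse(p$sev, r$sev),
    n = length(ids)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d speakers\n", x$n))
  cat(sprintf("  intelligibility: rho = %.3f, RMSE = %.3f\n",
              x$spearman_int, x$rmse_int))
  cat(sprintf("  severity:        rho = %.3f, RMSE = %.3f\n",
              x$spearman_sev, x$rmse_sev))
  invisible(x)
}

#' Read / write a ratings matrix as TSV
#'
#' Header row of judge ids, first column of subject ids.
#' @param r a \code{ratings_matrix} (write) or path (read).
#' @param path file path.
#' @return the path (write) or a \code{ratings_matrix} (read).
#' @export
write_ratings_tsv <- function(r, path) {
  df <- data.frame(subject = rownames(r), as.data.frame(unclass(r)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_tsv
#' @export
read_ratings_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  ratings_matrix(m)
}
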