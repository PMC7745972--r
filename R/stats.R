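# round half away from zero at `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification accuracy as a printed percentage
#'
#' `100 * k / n`, rounded half-up at the requested number of decimals (one
#' for most printed tables, two where the printed figure has two).
#'
#' @param k correctly identified count.
#' @param n test-set size (> 0).
#' @param digits decimals of the printed figure; default 1.
#' @return percentage.
#' @export
accuracy_percent <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, digits)
}

#' Binomial standard error of an accuracy, in percent
#'
#' `100 * sqrt(p (1 - p) / n)` with `p = k/n`, rounded half-up.
#'
#' @inheritParams accuracy_percent
#' @return percentage standard error.
#' @export
binomial_se_percent <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0, k <= n)
  p <- k / n
  round_half_up(100 * sqrt(p * (1 - p) / n), digits)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, k, n - k + 1)` (0 when k = 0),
#' upper = `qbeta(1 - alpha/2, k + 1, n - k)` (1 when k = n).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, > 0.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return named numeric `c(lower = , upper = )` proportions.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(n > 0, k >= 0, k <= n)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Inverse-frequency class weights
#'
#' One weight per class, `total / class_count`, so that the weighted mass of
#' every class equals the dataset total — counteracting class imbalance in
#' training.
#'
#' @param counts named numeric vector of per-class image counts (> 0).
#' @return named numeric vector of weights.
#' @export
class_weights <- function(counts) {
  counts <- unlist(counts)
  if (any(counts <= 0)) stop("class counts must all be > 0")
  sum(counts) / counts
}

#' Summarize a directory of metadata records
#'
#' Reads every `.json` metadata record in a run directory and tallies
#' subimages by label. Unreadable or invalid records are reported via a
#' warning, skipped, and counted.
#'
#' @param dir directory containing metadata `.json` files (searched
#'   recursively).
#' @return list with `counts` (data.frame `label`, `n_subimages`, sorted by
#'   label), `total`, `n_records`, `n_unreadable`.
#' @export
dataset_summary <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE,
                      recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  labels <- character(0)
  n_bad <- 0L; n_rec <- 0L
  for (f in files) {
    rec <- tryCatch(read_metadata(f), error = function(e) NULL)
    if (is.null(rec)) {
      warning("skipping unreadable metadata record: ", f)
      n_bad <- n_bad + 1L
      next
    }
    n_rec <- n_rec + 1L
    labels <- c(labels, vapply(rec$bounding_boxes, `[[`, character(1), "label"))
  }
  counts <- if (length(labels)) {
    tb <- table(labels)
    data.frame(label = names(tb), n_subimages = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(0), n_subimages = integer(0))
  list(counts = counts[order(counts$label), , drop = FALSE],
       total = length(labels), n_records = n_rec, n_unreadable = n_bad)
}

#' Write a dataset summary as CSV and plain text
#'
#' @param summary as returned by [dataset_summary()].
#' @param csv_path,txt_path optional output paths.
#' @return invisibly, the summary.
#' @export
write_summary <- function(summary, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary$counts, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    lines <- c(sprintf("%-28s %8s", "Label", "Images"),
               sprintf("%-28s %8d", summary$counts$label, summary$counts$n_subimages),
               sprintf("%-28s %8d", "Total", summary$total))
    writeLines(lines, txt_path)
  }
  invisible(summary)
}
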