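#' Construct a two-class expression experiment
#'
#' Bundles a genes-by-samples matrix of log2-scale expression indices with a
#' binary class assignment. This is the unit of input for every per-gene
#' statistic in the package: fold changes are differences of class-mean log2
#' expression, so the matrix must already be on the log scale.
#'
#' Rows with any missing value are dropped at construction (with a message
#' reporting the count), matching the ingestion policy for processed
#' expression indices; gene identifiers must be unique, which is guaranteed
#' downstream of [collapse_probesets()].
#'
#' @param expr Numeric matrix, genes in rows (rownames are gene identifiers),
#'   samples in columns.
#' @param labels Class assignment for each column of `expr`; character or
#'   factor with exactly two distinct values, each appearing at least twice.
#'   A named vector is matched against `colnames(expr)`.
#' @param species Free-text tag (e.g. `"mouse"`, `"human"`), kept for
#'   provenance only.
#' @param classes Optional length-2 character vector fixing which label is
#'   class 1 and which is class 2 (fold change is class 1 minus class 2).
#'   Defaults to the sorted unique labels.
#' @return An object of class `two_class_experiment`: a list with elements
#'   `expr`, `labels` (factor with levels `classes`), and `species`.
#' @seealso [compute_gene_stats()], [read_expression_table()]
#' @export
two_class_experiment <- function(expr, labels, species = "unknown",
                                 classes = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr))) {
    stop("`expr` must have rownames giving gene identifiers", call. = FALSE)
  }
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels)) && !is.null(colnames(expr))) {
    if (!all(colnames(expr) %in% names(labels))) {
      missing_n <- sum(!colnames(expr) %in% names(labels))
      message("dropping ", missing_n, " unlabeled sample(s)")
      expr <- expr[, colnames(expr) %in% names(labels), drop = FALSE]
    }
    labels <- labels[colnames(expr)]
  }
  if (length(labels) != ncol(expr)) {
    stop("`labels` must have one entry per sample column", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("gene identifiers must be unique; collapse probe sets first",
         call. = FALSE)
  }
  n_na <- sum(!stats::complete.cases(expr))
  if (n_na > 0) {
    message("dropping ", n_na, " gene row(s) with missing values")
    expr <- expr[stats::complete.cases(expr), , drop = FALSE]
  }
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) != 2 || !all(labels %in% classes)) {
    stop("labels must take exactly two values; got: ",
         paste(unique(labels), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) {
    stop("invalid design: each class needs at least 2 samples (",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(
    list(expr = expr,
         labels = factor(labels, levels = classes),
         species = species),
    class = "two_class_experiment"
  )
}

#' @export
print.two_class_experiment <- function(x, ...) {
  counts <- table(x$labels)
  cat("<two_class_experiment> ", x$species, ": ",
      nrow(x$expr), " genes, ",
      paste(sprintf("%s n=%d", names(counts), counts), collapse = " vs "),
      "\n", sep = "")
  invisible(x)
}

#' Pooled within-class standard deviation
#'
#' Combines the two class standard deviations of a two-class design into a
#' single within-class SD,
#' \deqn{s = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}},}
#' the usual pooled estimate underlying the equal-variance two-sample t-test.
#' All arguments are vectorised.
#'
#' @param sd1,sd2 Nonnegative per-class standard deviations.
#' @param n1,n2 Class sample sizes; both must be at least 2 so each class
#'   contributes at least one degree of freedom.
#' @return Pooled SD, same length as the inputs.
#' @examples
#' pooled_within_class_sd(0.4, 0.4, 5, 9)   # equal SDs pool to themselves
#' pooled_within_class_sd(0.3, 0.4, 3, 5)
#' @export
pooled_within_class_sd <- function(sd1, sd2, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("invalid design: n1 and n2 must each be >= 2", call. = FALSE)
  }
  if (any(sd1 < 0) || any(sd2 < 0)) {
    stop("class standard deviations must be nonnegative", call. = FALSE)
  }
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Modified z-score magnitude of an expression change
#'
#' The fold-change-to-noise ratio used throughout the package, with small
#' fold changes truncated to a fixed offset so that near-zero changes do not
#' produce unstable ratios:
#' \deqn{z = \frac{(|f| - \delta)_+ + \delta}{s},}
#' where \eqn{(x)_+ = \max(x, 0)}. The result is a magnitude, bounded below
#' by \eqn{\delta/s}; the direction of change is carried separately as
#' `sign(f)`.
#'
#' @param f Fold change (difference of class-mean log2 expression).
#' @param s Pooled within-class SD, strictly positive (floored upstream).
#' @param delta Truncation offset on the log2 fold-change scale; default
#'   `0.25`.
#' @return Positive modified z magnitude, vectorised over the inputs.
#' @examples
#' modified_z(0.1, 0.5)          # |f| below delta: truncated, 0.25/0.5
#' modified_z(-0.6, 0.5)         # ((0.6 - 0.25) + 0.25)/0.5 = 1.2
#' @export
modified_z <- function(f, s, delta = 0.25) {
  if (any(s <= 0)) {
    stop("degenerate input: s must be > 0 (apply the SD floor upstream)",
         call. = FALSE)
  }
  if (any(delta <= 0)) stop("`delta` must be > 0", call. = FALSE)
  (pmax(abs(f) - delta, 0) + delta) / s
}

#' Per-gene two-class summary statistics
#'
#' Computes, for every gene of a [two_class_experiment()], the fold change
#' `f` (class-1 mean minus class-2 mean of log2 expression), the pooled
#' within-class SD `s` (see [pooled_within_class_sd()]), the class sample
#' sizes and the direction of change `sign(f)`. Constant genes would give
#' `s = 0`, so `s` is floored at `sd_floor` to keep downstream ratios
#' defined.
#'
#' @param exp A [two_class_experiment()].
#' @param sd_floor Lower bound applied to the pooled SD; default `1e-6`.
#' @return A tibble with columns `gene_id`, `f`, `s`, `n1`, `n2`,
#'   `direction`.
#' @examples
#' expr <- matrix(c(2, 2, 2, 1, 1, 1, 5, 5, 5, 5, 5, 5),
#'                nrow = 2, byrow = TRUE,
#'                dimnames = list(c("up", "flat"), NULL))
#' exp <- two_class_experiment(expr, rep(c("a", "b"), each = 3))
#' compute_gene_stats(exp)
#' @export
compute_gene_stats <- function(exp, sd_floor = 1e-6) {
  stopifnot(inherits(exp, "two_class_experiment"))
  cls <- levels(exp$labels)
  x1 <- exp$expr[, exp$labels == cls[1], drop = FALSE]
  x2 <- exp$expr[, exp$labels == cls[2], drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  sd1 <- sqrt(rowSums((x1 - m1)^2) / (n1 - 1))
  sd2 <- sqrt(rowSums((x2 - m2)^2) / (n2 - 1))
  f <- m1 - m2
  tibble::tibble(
    gene_id = rownames(exp$expr),
    f = unname(f),
    s = pmax(unname(pooled_within_class_sd(sd1, sd2, n1, n2)), sd_floor),
    n1 = n1,
    n2 = n2,
    direction = sign(unname(f))
  )
}
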