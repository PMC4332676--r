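#' Pseudo-variance penalized t-statistic
#'
#' The two-sample t-statistic of a two-class comparison with the gene's
#' pseudo variance added to the pooled within-class SD:
#' \deqn{t = \frac{f}{(s+\alpha)\sqrt{1/n_1 + 1/n_2}}.}
#' With `alpha = 0` this is the ordinary pooled two-sample t; a positive
#' `alpha` shrinks the statistic toward zero, so the penalty can only
#' reduce significance.
#'
#' @param f Fold change.
#' @param s Pooled within-class SD (floored, strictly positive).
#' @param alpha Nonnegative pseudo variance on the SD scale.
#' @param n1,n2 Class sample sizes.
#' @return t-statistic, vectorised.
#' @examples
#' penalized_t(1.0, 0.5, 0.5, 8, 8)  # 2.0
#' @export
penalized_t <- function(f, s, alpha, n1, n2) {
  if (any(alpha < 0)) stop("`alpha` must be nonnegative", call. = FALSE)
  if (any(s <= 0)) stop("`s` must be > 0 (floored upstream)", call. = FALSE)
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("invalid design: n1 and n2 must each be >= 2", call. = FALSE)
  }
  f / ((s + alpha) * sqrt(1 / n1 + 1 / n2))
}

#' Two-sided p-value for a (penalized) t-statistic
#'
#' Tail probability under Student's t with `n1 + n2 - 2` degrees of
#' freedom; penalized statistics are referred to the same distribution as
#' unpenalized ones, which makes the penalized test conservative.
#'
#' @param t t-statistic.
#' @param n1,n2 Class sample sizes; `n1 + n2 - 2` must be at least 1.
#' @return Two-sided p-value in (0, 1], vectorised.
#' @export
p_value <- function(t, n1, n2) {
  df <- n1 + n2 - 2
  if (any(df < 1)) stop("invalid design: df = n1 + n2 - 2 must be >= 1",
                        call. = FALSE)
  2 * stats::pt(-abs(t), df = df)
}

#' Translate a model-organism experiment
#'
#' Runs the per-gene differential-expression analysis of a new two-class
#' model-organism experiment, either penalized by trained pseudo variances
#' (`mode = "ebt"`) or unpenalized (`mode = "conventional"`, the baseline
#' that treats every model gene as translating perfectly). Genes of the
#' test experiment that are absent from the pseudo-variance table receive
#' `alpha = 0` (a warning reports the count), so the two modes are always
#' computed on the same gene universe.
#'
#' @param test A [two_class_experiment()], or a precomputed gene-stats
#'   tibble from [compute_gene_stats()].
#' @param table An `ebt_pseudovar` table from [train_pseudo_variances()];
#'   may be `NULL` in conventional mode.
#' @param mode `"ebt"` or `"conventional"`.
#' @param sd_floor Passed to [compute_gene_stats()] when `test` is an
#'   experiment.
#' @return A tibble of class `ebt_translation` with columns `gene_id`, `f`,
#'   `s`, `alpha`, `t`, `p`, `padj` (Benjamini-Hochberg, provided for
#'   convenience and unused by the packaged evaluations), `direction`,
#'   `mode`.
#' @examples
#' \dontrun{
#' res_ebt <- translate_experiment(test_exp, pv, mode = "ebt")
#' res_ct  <- translate_experiment(test_exp, NULL, mode = "conventional")
#' }
#' @export
translate_experiment <- function(test, table = NULL,
                                 mode = c("ebt", "conventional"),
                                 sd_floor = 1e-6) {
  mode <- match.arg(mode)
  stats_tab <- if (inherits(test, "two_class_experiment")) {
    compute_gene_stats(test, sd_floor = sd_floor)
  } else {
    stopifnot(is.data.frame(test),
              all(c("gene_id", "f", "s", "n1", "n2") %in% names(test)))
    test
  }
  if (mode == "ebt") {
    if (is.null(table)) {
      stop("configuration error: ebt mode requires a pseudo-variance table",
           call. = FALSE)
    }
    idx <- match(stats_tab$gene_id, table$gene_id)
    if (!any(!is.na(idx))) {
      stop("configuration error: no genes shared between test experiment ",
           "and pseudo-variance table", call. = FALSE)
    }
    n_missing <- sum(is.na(idx))
    if (n_missing > 0) {
      warning(n_missing, " test gene(s) absent from the pseudo-variance ",
              "table; using alpha = 0 for them", call. = FALSE)
    }
    alpha <- ifelse(is.na(idx), 0, table$alpha[idx])
  } else {
    alpha <- rep(0, nrow(stats_tab))
  }
  t_stat <- penalized_t(stats_tab$f, stats_tab$s, alpha,
                        stats_tab$n1, stats_tab$n2)
  p <- p_value(t_stat, stats_tab$n1, stats_tab$n2)
  out <- tibble::tibble(
    gene_id = stats_tab$gene_id,
    f = stats_tab$f,
    s = stats_tab$s,
    alpha = alpha,
    t = t_stat,
    p = p,
    padj = stats::p.adjust(p, method = "BH"),
    direction = sign(stats_tab$f),
    mode = mode
  )
  class(out) <- c("ebt_translation", class(out))
  out
}

#' Write / read a translation results table
#'
#' Tab-separated results with a stable column order (`gene_id`, `f`, `s`,
#' `alpha`, `t`, `p`, `padj`, `direction`, `mode`); numeric columns are
#' formatted to 6 significant digits. `#`-prefixed header lines are
#' ignored on read and may be supplied on write.
#'
#' @param results An `ebt_translation` tibble.
#' @param path File path.
#' @param extra_header Optional named character vector of `# key: value`
#'   header lines.
#' @export
write_translation <- function(results, path, extra_header = NULL) {
  stopifnot(is.data.frame(results))
  num <- function(x) sprintf("%.6g", x)
  header <- c(
    paste0("# ebtrans translation v", utils::packageVersion("ebtrans")),
    if (!is.null(extra_header)) paste0("# ", names(extra_header), ": ",
                                       extra_header)
  )
  body <- paste(results$gene_id, num(results$f), num(results$s),
                num(results$alpha), num(results$t), num(results$p),
                num(results$padj), results$direction, results$mode,
                sep = "\t")
  writeLines(c(header,
               "gene_id\tf\ts\talpha\tt\tp\tpadj\tdirection\tmode",
               body), path)
  invisible(path)
}

#' @rdname write_translation
#' @export
read_translation <- function(path) {
  out <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           mode = readr::col_character(),
                           .default = readr::col_double()
                         ))
  class(out) <- c("ebt_translation", class(out))
  out
}
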