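#' Direct pseudo-variance estimate for sign-concordant genes
#'
#' For a gene whose expression change has the same direction in the model
#' and target systems of a training pair, the pseudo variance `alpha` is the
#' nonnegative penalty on the model SD that matches the two modified
#' z-score magnitudes:
#' \deqn{\alpha^* = \mathrm{argmin}_{\alpha \ge 0}
#'   \left(\frac{g_m}{s_m+\alpha} - \frac{g_t}{s_t}\right)^2,}
#' where \eqn{g = (|f|-\delta)_+ + \delta}. The minimizer has the closed
#' form \eqn{\max(0, g_m s_t / g_t - s_m)}: when the model change is already
#' no stronger than the target's (relative to noise) no penalty is needed.
#'
#' @param fm,sm Fold change and pooled SD in the model experiment.
#' @param ft,st Fold change and pooled SD in the target experiment.
#' @param delta Modified z-score offset; default `0.25`.
#' @return Nonnegative `alpha` on the SD scale, vectorised.
#' @examples
#' alpha_same_sign(1.0, 0.5, 0.5, 0.5)  # 0.5: model z twice the target z
#' alpha_same_sign(0.8, 0.4, 0.8, 0.4)  # 0: identical z-scores
#' @export
alpha_same_sign <- function(fm, sm, ft, st, delta = 0.25) {
  if (any(sm <= 0) || any(st <= 0)) {
    stop("degenerate input: sm and st must be > 0", call. = FALSE)
  }
  gm <- pmax(abs(fm) - delta, 0) + delta
  gt <- pmax(abs(ft) - delta, 0) + delta
  # single-division form: exact zero when the two z-scores coincide
  pmax(0, (gm * st - gt * sm) / gt)
}

#' Fit the log-linear pseudo-variance imputation model
#'
#' Genes whose change directions disagree between model and target cannot be
#' matched by [alpha_same_sign()]; their pseudo variances are instead
#' predicted from a linear model of the log pseudo variance on the logged
#' modified z-score difference and the two within-class SDs,
#' fitted by ordinary least squares on the sign-concordant training genes
#' that received a strictly positive direct estimate (for those genes
#' \eqn{z_m > z_t}, so the log of the difference is defined).
#'
#' @param training Tibble of paired per-gene statistics with columns
#'   `f_m`, `s_m`, `f_t`, `s_t` (see [join_orthologs()]).
#' @param alphas Direct pseudo variances for the rows of `training`, as from
#'   [alpha_same_sign()]; rows with `NA` (e.g. discordant genes) are ignored.
#' @param delta Modified z-score offset; default `0.25`.
#' @param min_fit Minimum number of positive-alpha genes required; default
#'   `10`.
#' @return An object of class `ebt_imputation_model`: list with `coef`
#'   (named vector: `intercept`, `log_zdiff`, `s_m`, `s_t`), `n_fit`,
#'   `sigma` (residual SD) and `delta`.
#' @export
fit_imputation_model <- function(training, alphas, delta = 0.25,
                                 min_fit = 10) {
  keep <- !is.na(alphas) & alphas > 0
  n_fit <- sum(keep)
  if (n_fit < min_fit) {
    stop("training insufficient: only ", n_fit,
         " sign-concordant genes with positive pseudo variance (need >= ",
         min_fit, ")", call. = FALSE)
  }
  tr <- training[keep, ]
  zm <- modified_z(tr$f_m, tr$s_m, delta)
  zt <- modified_z(tr$f_t, tr$s_t, delta)
  # alphas from the direct minimization guarantee zm > zt; user-supplied
  # alphas may not, so guard the log
  ok <- zm > zt
  if (!all(ok)) {
    tr <- tr[ok, ]
    zm <- zm[ok]
    zt <- zt[ok]
    n_fit <- sum(ok)
    if (n_fit < min_fit) {
      stop("training insufficient: only ", n_fit,
           " usable positive-alpha genes (need >= ", min_fit, ")",
           call. = FALSE)
    }
  }
  dat <- data.frame(
    log_alpha = log(alphas[keep][ok]),
    log_zdiff = log(zm - zt),
    s_m = tr$s_m,
    s_t = tr$s_t
  )
  fit <- stats::lm(log_alpha ~ log_zdiff + s_m + s_t, data = dat)
  coefs <- stats::coef(fit)
  structure(
    list(
      coef = c(intercept = unname(coefs[["(Intercept)"]]),
               log_zdiff = unname(coefs[["log_zdiff"]]),
               s_m = unname(coefs[["s_m"]]),
               s_t = unname(coefs[["s_t"]])),
      n_fit = n_fit,
      sigma = stats::sigma(fit),
      r_squared = summary(fit)$r.squared,
      delta = delta
    ),
    class = "ebt_imputation_model"
  )
}

#' @export
print.ebt_imputation_model <- function(x, ...) {
  cat("<ebt_imputation_model> log(alpha) ~ log(z_m - z_t) + s_m + s_t\n")
  print(round(x$coef, 4))
  cat("fitted on", x$n_fit, "genes; residual SD", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' @rdname fit_imputation_model
#' @param x An `ebt_imputation_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ebt_imputation_model <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname fit_imputation_model
#' @exportS3Method generics::glance
glance.ebt_imputation_model <- function(x, ...) {
  tibble::tibble(n_fit = x$n_fit, sigma = x$sigma,
                 r.squared = x$r_squared, delta = x$delta)
}

#' Imputed pseudo variance for sign-discordant genes
#'
#' Applies a fitted [fit_imputation_model()] to genes whose change
#' directions differ between model and target. For such genes the signed
#' modified z-scores lie on opposite sides of zero, so the magnitude of
#' their difference is the sum of the two magnitudes; the model's logged
#' z-difference predictor is therefore \eqn{\log(z_m + z_t)} (magnitudes
#' from [modified_z()]). The prediction is back-transformed by
#' exponentiation and clipped at zero (a safeguard that is a no-op on the
#' log scale, where predictions are always positive).
#'
#' @inheritParams alpha_same_sign
#' @param model A fitted `ebt_imputation_model`.
#' @return Nonnegative `alpha`, vectorised.
#' @export
alpha_opposite_sign <- function(fm, sm, ft, st, model, delta = 0.25) {
  if (!inherits(model, "ebt_imputation_model")) {
    stop("fit the imputation model before imputing opposite-sign genes",
         call. = FALSE)
  }
  zm <- modified_z(fm, sm, delta)
  zt <- modified_z(ft, st, delta)
  pred <- model$coef[["intercept"]] +
    model$coef[["log_zdiff"]] * log(zm + zt) +
    model$coef[["s_m"]] * sm +
    model$coef[["s_t"]] * st
  pmax(0, exp(pred))
}

#' Train per-gene pseudo variances from a paired experiment
#'
#' The two-step estimator at the core of evidence-based translation. Genes
#' whose training changes share a direction (including genes with a zero
#' direction on either side, for which the truncated z-scores are still
#' well defined) get a direct estimate from [alpha_same_sign()]; the
#' imputation model is then fitted on the direct estimates that are
#' strictly positive, and genes with opposite directions get an imputed
#' estimate from [alpha_opposite_sign()].
#'
#' @param training Tibble of paired per-gene training statistics with
#'   columns `gene_id`, `f_m`, `s_m`, `f_t`, `s_t` (from
#'   [join_orthologs()] or assembled by hand).
#' @param delta Modified z-score offset; default `0.25`.
#' @param tranche_threshold Boundary between "moderate" and "large" pseudo
#'   variances in the summary tranches, on the same SD scale as `alpha`;
#'   default `0.25` (i.e. `0.5^2`).
#' @param min_fit Passed to [fit_imputation_model()].
#' @return An object of class `ebt_pseudovar`: a tibble with columns
#'   `gene_id`, `alpha`, `provenance` (`"direct"` or `"imputed"`), carrying
#'   the fitted imputation model, `delta`, `tranche_threshold` and tranche
#'   counts as attributes. Access the per-gene table with `tidy()` and the
#'   training summary with `glance()`.
#' @examples
#' tr <- tibble::tibble(
#'   gene_id = paste0("g", 1:200),
#'   f_m = rnorm(200, 1), s_m = runif(200, 0.3, 0.6),
#'   f_t = rnorm(200, 1), s_t = runif(200, 0.3, 0.6)
#' )
#' pv <- train_pseudo_variances(tr)
#' glance(pv)
#' @export
train_pseudo_variances <- function(training, delta = 0.25,
                                   tranche_threshold = 0.25, min_fit = 10) {
  stopifnot(is.data.frame(training), nrow(training) > 0)
  req <- c("gene_id", "f_m", "s_m", "f_t", "s_t")
  if (!all(req %in% names(training))) {
    stop("`training` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  dm <- sign(training$f_m)
  dt <- sign(training$f_t)
  concordant <- dm == dt | dm == 0 | dt == 0

  alpha <- rep(NA_real_, nrow(training))
  alpha[concordant] <- alpha_same_sign(
    training$f_m[concordant], training$s_m[concordant],
    training$f_t[concordant], training$s_t[concordant], delta
  )
  direct_for_fit <- ifelse(concordant, alpha, NA_real_)
  # the imputation model is only needed (and only fittable) when there is
  # something to impute; a perfect training pair has neither
  model <- NULL
  if (any(!concordant) || sum(direct_for_fit > 0, na.rm = TRUE) >= min_fit) {
    model <- fit_imputation_model(training, direct_for_fit, delta,
                                  min_fit = min_fit)
  }
  if (any(!concordant)) {
    alpha[!concordant] <- alpha_opposite_sign(
      training$f_m[!concordant], training$s_m[!concordant],
      training$f_t[!concordant], training$s_t[!concordant], model, delta
    )
  }
  tab <- tibble::tibble(
    gene_id = training$gene_id,
    alpha = alpha,
    provenance = ifelse(concordant, "direct", "imputed")
  )
  tranches <- c(
    zero = sum(alpha == 0),
    moderate = sum(alpha > 0 & alpha <= tranche_threshold),
    large = sum(alpha > tranche_threshold)
  )
  message(sprintf(
    "pseudo variances: %d genes (%d direct, %d imputed); alpha = 0: %d, 0 < alpha <= %g: %d, alpha > %g: %d",
    nrow(tab), sum(concordant), sum(!concordant),
    tranches[["zero"]], tranche_threshold, tranches[["moderate"]],
    tranche_threshold, tranches[["large"]]
  ))
  structure(
    tab,
    class = c("ebt_pseudovar", class(tab)),
    imputation_model = model,
    delta = delta,
    tranche_threshold = tranche_threshold,
    tranches = tranches
  )
}

#' @rdname train_pseudo_variances
#' @param x An `ebt_pseudovar` table.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ebt_pseudovar <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "alpha", "provenance")])
}

#' @rdname train_pseudo_variances
#' @exportS3Method generics::glance
glance.ebt_pseudovar <- function(x, ...) {
  tr <- attr(x, "tranches")
  tibble::tibble(
    n_genes = nrow(x),
    n_direct = sum(x$provenance == "direct"),
    n_imputed = sum(x$provenance == "imputed"),
    n_alpha_zero = tr[["zero"]],
    n_alpha_moderate = tr[["moderate"]],
    n_alpha_large = tr[["large"]],
    delta = attr(x, "delta"),
    tranche_threshold = attr(x, "tranche_threshold")
  )
}

#' Write / read a pseudo-variance table
#'
#' The on-disk format is a tab-separated three-column table
#' (`gene_id`, `alpha`, `provenance`) preceded by `#`-prefixed header lines
#' carrying the offset `delta`, the tranche threshold and the imputation
#' model (coefficients, fit size, residual SD). Numeric values are written
#' with 15 significant digits so a round trip is lossless well beyond 12
#' significant digits.
#'
#' @param pv An `ebt_pseudovar` object.
#' @param path File path.
#' @param extra_header Optional named character vector of additional
#'   `# key: value` header lines (used by the CLI for its provenance block).
#' @return `write_pseudovar()` returns `path` invisibly; `read_pseudovar()`
#'   returns an `ebt_pseudovar` object.
#' @export
write_pseudovar <- function(pv, path, extra_header = NULL) {
  stopifnot(inherits(pv, "ebt_pseudovar"))
  m <- attr(pv, "imputation_model")
  num <- function(x) sprintf("%.15g", x)
  header <- c(
    paste0("# ebtrans pseudovar v", utils::packageVersion("ebtrans")),
    paste0("# delta: ", num(attr(pv, "delta"))),
    paste0("# tranche_threshold: ", num(attr(pv, "tranche_threshold"))),
    paste0("# model_intercept: ", if (is.null(m)) "NA" else num(m$coef[["intercept"]])),
    paste0("# model_coef_log_zdiff: ", if (is.null(m)) "NA" else num(m$coef[["log_zdiff"]])),
    paste0("# model_coef_s_m: ", if (is.null(m)) "NA" else num(m$coef[["s_m"]])),
    paste0("# model_coef_s_t: ", if (is.null(m)) "NA" else num(m$coef[["s_t"]])),
    paste0("# model_n_fit: ", if (is.null(m)) "NA" else m$n_fit),
    paste0("# model_sigma: ", if (is.null(m)) "NA" else num(m$sigma)),
    if (!is.null(extra_header)) paste0("# ", names(extra_header), ": ",
                                       extra_header)
  )
  body <- paste(pv$gene_id, num(pv$alpha), pv$provenance, sep = "\t")
  writeLines(c(header, "gene_id\talpha\tprovenance", body), path)
  invisible(path)
}

#' @rdname write_pseudovar
#' @export
read_pseudovar <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) != 1) stop("malformed pseudovar header: missing ", key,
                              call. = FALSE)
    sub(paste0("^# ", key, ": "), "", ln)
  }
  tab <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           alpha = readr::col_double(),
                           provenance = readr::col_character()
                         ), progress = FALSE)
  model <- if (identical(get("model_intercept"), "NA")) NULL else structure(
    list(coef = c(intercept = as.numeric(get("model_intercept")),
                  log_zdiff = as.numeric(get("model_coef_log_zdiff")),
                  s_m = as.numeric(get("model_coef_s_m")),
                  s_t = as.numeric(get("model_coef_s_t"))),
         n_fit = as.integer(get("model_n_fit")),
         sigma = as.numeric(get("model_sigma")),
         r_squared = NA_real_,
         delta = as.numeric(get("delta"))),
    class = "ebt_imputation_model"
  )
  tranche_threshold <- as.numeric(get("tranche_threshold"))
  structure(
    tab,
    class = c("ebt_pseudovar", class(tab)),
    imputation_model = model,
    delta = as.numeric(get("delta")),
    tranche_threshold = tranche_threshold,
    tranches = c(zero = sum(tab$alpha == 0),
                 moderate = sum(tab$alpha > 0 & tab$alpha <= tranche_threshold),
                 large = sum(tab$alpha > tranche_threshold))
  )
}
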