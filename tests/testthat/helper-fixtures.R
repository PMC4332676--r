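# Shared fixture builders. Everything is generated in code; no stored data.

# A small two-class experiment with per-gene effects `f` (case minus
# control) and common within-class noise sd.
make_experiment <- function(f, n_per_class = 4, noise_sd = 0.3,
                            species = "mouse", prefix = "g", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(f)
  expr <- cbind(
    matrix(rep(f / 2, n_per_class), ncol = n_per_class),
    matrix(rep(-f / 2, n_per_class), ncol = n_per_class)
  ) + stats::rnorm(n * 2 * n_per_class, 0, noise_sd)
  rownames(expr) <- sprintf("%s%03d", prefix, seq_len(n))
  colnames(expr) <- sprintf("s%02d", seq_len(2 * n_per_class))
  two_class_experiment(expr, rep(c("case", "control"), each = n_per_class),
                       species = species)
}

# A paired training table with controllable sign structure.
make_training <- function(n = 200, frac_discordant = 0, seed = 1,
                          effect_sd = 1, sd_range = c(0.3, 0.6)) {
  set.seed(seed)
  base <- stats::rnorm(n, 0, effect_sd)
  disc <- seq_len(n) <= round(n * frac_discordant)
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    f_m = base + stats::rnorm(n, 0, 0.1),
    s_m = stats::runif(n, sd_range[1], sd_range[2]),
    f_t = ifelse(disc, -1, 1) * (base + stats::rnorm(n, 0, 0.1)),
    s_t = stats::runif(n, sd_range[1], sd_range[2])
  )
}

# Exact hypergeometric upper-tail oracle, from binomial coefficients only.
hyper_tail_oracle <- function(k, n_set, n_univ, n_sel) {
  ks <- seq(k, min(n_set, n_sel))
  if (length(ks) == 0 || k <= 0) return(1)
  sum(choose(n_set, ks) * choose(n_univ - n_set, n_sel - ks)) /
    choose(n_univ, n_sel)
}
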