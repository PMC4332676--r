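#' Configuration for a synthetic paired translation study
#'
#' Describes a paired model/target, train/test study with known
#' translation structure. Genes fall into three categories in exact
#' configured proportions: *concordant* genes respond with the same true
#' effect in both species, *discordant* genes respond with the opposite
#' sign in the target, and *null* genes do not respond. Defaults emulate a
#' strong immune-stimulation contrast on expression microarrays: true
#' effects drawn from N(0, 1) on the log2 scale and per-gene within-class
#' SDs uniform on 0.2-0.6.
#'
#' @param n_genes Number of genes; default `10000`.
#' @param n_per_class Samples per class in every experiment; default `8`.
#' @param frac_concordant,frac_discordant,frac_null Gene-category
#'   proportions, must sum to 1; defaults `0.3`, `0.3`, `0.4`.
#' @param effect_sd SD of the true effect-size distribution (log2 scale);
#'   default `1`.
#' @param noise_sd_range Length-2 interval for per-gene within-class SDs;
#'   default `c(0.2, 0.6)`.
#' @param frac_test_flip Fraction of non-null genes whose effect direction
#'   flips between train and test (both species for concordant genes,
#'   model side only for discordant genes); default `0.1`.
#' @param seed Integer seed; mandatory, the study is fully reproducible
#'   from it.
#' @param discordance `"negated"` (target effect is minus the model
#'   effect, the default, which makes discordance unambiguous) or
#'   `"independent"` (target effect drawn independently with the opposite
#'   sign).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 10000, n_per_class = 8,
                             frac_concordant = 0.3, frac_discordant = 0.3,
                             frac_null = 0.4, effect_sd = 1,
                             noise_sd_range = c(0.2, 0.6),
                             frac_test_flip = 0.1, seed,
                             discordance = c("negated", "independent")) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  fracs <- c(frac_concordant = frac_concordant,
             frac_discordant = frac_discordant, frac_null = frac_null)
  if (any(fracs < 0) || any(fracs > 1) ||
      abs(sum(fracs) - 1) > 1e-8) {
    stop("config error: frac_concordant, frac_discordant and frac_null ",
         "must lie in [0,1] and sum to 1 (got ",
         paste(sprintf("%s=%g", names(fracs), fracs), collapse = ", "), ")",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1, n_per_class >= 2, effect_sd > 0,
            length(noise_sd_range) == 2, all(noise_sd_range > 0),
            noise_sd_range[1] <= noise_sd_range[2],
            frac_test_flip >= 0, frac_test_flip <= 1)
  structure(
    list(n_genes = as.integer(n_genes),
         n_per_class = as.integer(n_per_class),
         frac_concordant = frac_concordant,
         frac_discordant = frac_discordant,
         frac_null = frac_null,
         effect_sd = effect_sd,
         noise_sd_range = noise_sd_range,
         frac_test_flip = frac_test_flip,
         seed = as.integer(seed),
         discordance = match.arg(discordance)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic paired translation study
#'
#' Draws the four two-class experiments of a paired study (model/target x
#' train/test) plus the per-gene ground truth. Per gene: a category in
#' exact configured proportions, a within-class noise SD uniform on
#' `noise_sd_range`, and a base effect ~ N(0, `effect_sd`^2). Training
#' effects share the base effect's sign across species (concordant),
#' oppose it (discordant) or are zero (null); test effects reuse the
#' training effects, with a sign flip applied to a `frac_test_flip` subset
#' of non-null genes. Samples are drawn as a per-gene baseline plus or
#' minus half the effect (class `"case"` vs `"control"`) plus Gaussian
#' within-class noise. Model genes use Title-case symbols and target genes
#' the upper-case orthologs, joined by the returned map.
#'
#' Sets the RNG seed from `config$seed`; the output is bit-identical across
#' runs for a given configuration.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `model_train`, `target_train`, `model_test`,
#'   `target_test` ([two_class_experiment()]s), `truth` (tibble:
#'   `gene_id` (target symbol), `model_symbol`, `category`, `noise_sd`,
#'   `effect_model_train`, `effect_target_train`, `effect_model_test`,
#'   `effect_target_test`, `flip`), `ortholog_map`, and `config`.
#' @export
generate_paired_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  counts <- c(
    concordant = floor(n * config$frac_concordant),
    discordant = floor(n * config$frac_discordant)
  )
  counts <- c(counts, null = n - sum(counts))
  category <- sample(rep(names(counts), counts))

  model_symbol <- sprintf("Gene%05d", seq_len(n))
  target_symbol <- toupper(model_symbol)
  noise_sd <- stats::runif(n, config$noise_sd_range[1],
                           config$noise_sd_range[2])
  base <- stats::rnorm(n, 0, config$effect_sd)

  eff_m <- ifelse(category == "null", 0, base)
  eff_t <- dplyr::case_when(
    category == "null" ~ 0,
    category == "concordant" ~ base,
    config$discordance == "negated" ~ -base,
    .default = -sign(base) * abs(stats::rnorm(n, 0, config$effect_sd))
  )

  nonnull <- which(category != "null")
  n_flip <- round(config$frac_test_flip * length(nonnull))
  flip_idx <- if (n_flip > 0) sample(nonnull, n_flip) else integer()
  flip <- seq_len(n) %in% flip_idx

  eff_m_test <- ifelse(flip, -eff_m, eff_m)
  # concordant genes flip in both species; discordant genes model-only
  eff_t_test <- ifelse(flip & category == "concordant", -eff_t, eff_t)

  baseline <- stats::rnorm(n, 7, 2)
  draw_exp <- function(effect, species, phase, symbols) {
    k <- config$n_per_class
    means <- cbind(matrix(rep(baseline + effect / 2, k), ncol = k),
                   matrix(rep(baseline - effect / 2, k), ncol = k))
    expr <- means + stats::rnorm(n * 2 * k, 0, noise_sd)
    colnames(expr) <- sprintf("%s_%s_s%02d", species, phase,
                              seq_len(2 * k))
    rownames(expr) <- symbols
    two_class_experiment(expr, rep(c("case", "control"), each = k),
                         species = species)
  }
  study <- list(
    model_train = draw_exp(eff_m, "mouse", "train", model_symbol),
    target_train = draw_exp(eff_t, "human", "train", target_symbol),
    model_test = draw_exp(eff_m_test, "mouse", "test", model_symbol),
    target_test = draw_exp(eff_t_test, "human", "test", target_symbol),
    truth = tibble::tibble(
      gene_id = target_symbol,
      model_symbol = model_symbol,
      category = category,
      noise_sd = noise_sd,
      effect_model_train = eff_m,
      effect_target_train = eff_t,
      effect_model_test = eff_m_test,
      effect_target_test = eff_t_test,
      flip = flip
    ),
    ortholog_map = tibble::tibble(model_symbol = model_symbol,
                                  target_symbol = target_symbol),
    config = config
  )
  study
}

#' Benchmark the penalized translation against the conventional baseline
#'
#' Runs the full evaluation protocol on one synthetic study: trains pseudo
#' variances on the train pair, translates the model test experiment in
#' both modes, and scores direction agreement against the target test
#' experiment at the overall and experiment-specific layers.
#'
#' @param config A [synthetic_config()].
#' @param delta Modified z-score offset; default `0.25`.
#' @param theta Significance threshold for gene selection; default `0.05`.
#' @return Tibble with one row per mode x layer (`mode`, `layer`,
#'   `n_selected`, `n_agree`, `fraction`, `selection`) and attributes
#'   `improvement` (named vector of EBT minus conventional agreement per
#'   layer) and `pseudovar` (the trained table).
#' @export
benchmark_improvement <- function(config, delta = 0.25, theta = 0.05) {
  study <- generate_paired_study(config)
  paired <- join_orthologs(study$model_train, study$target_train,
                           study$ortholog_map)
  pv <- train_pseudo_variances(paired, delta = delta)

  model_test_mapped <- map_to_target_symbols(study$model_test,
                                             study$ortholog_map)
  model_train_mapped <- map_to_target_symbols(study$model_train,
                                              study$ortholog_map)
  res <- list(
    ebt = translate_experiment(model_test_mapped, pv, mode = "ebt"),
    conventional = translate_experiment(model_test_mapped, NULL,
                                        mode = "conventional")
  )
  stats_tabs <- list(
    model_train = compute_gene_stats(model_train_mapped),
    model_test = compute_gene_stats(model_test_mapped),
    target_train = compute_gene_stats(study$target_train),
    target_test = compute_gene_stats(study$target_test)
  )
  label <- sprintf("p<%g", theta)
  reports <- purrr::map_dfr(names(res), function(mode) {
    sel <- select_genes(res[[mode]], "p_threshold", theta = theta)
    dplyr::bind_rows(
      overall_agreement(sel, stats_tabs$model_test, stats_tabs$target_test,
                        selection = label),
      specific_response_agreement(sel, stats_tabs$model_train,
                                  stats_tabs$model_test,
                                  stats_tabs$target_train,
                                  stats_tabs$target_test,
                                  selection = label)
    ) |>
      dplyr::mutate(mode = mode, .before = 1)
  })
  wide <- reports |>
    dplyr::select("mode", "layer", "fraction") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "fraction")
  improvement <- stats::setNames(wide$ebt - wide$conventional, wide$layer)
  attr(reports, "improvement") <- improvement
  attr(reports, "pseudovar") <- pv
  reports
}

#' Write a synthetic study to the tabular exchange formats
#'
#' Emits the four expression matrices with label files (the format
#' [read_expression_table()] reads), the ortholog map, the truth table and
#' a YAML manifest recording the configuration and file checksums.
#'
#' @param study Output of [generate_paired_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    model_train = file.path(dir, "model_train.tsv"),
    model_train_labels = file.path(dir, "model_train_labels.tsv"),
    target_train = file.path(dir, "target_train.tsv"),
    target_train_labels = file.path(dir, "target_train_labels.tsv"),
    model_test = file.path(dir, "model_test.tsv"),
    model_test_labels = file.path(dir, "model_test_labels.tsv"),
    target_test = file.path(dir, "target_test.tsv"),
    target_test_labels = file.path(dir, "target_test_labels.tsv"),
    ortholog_map = file.path(dir, "ortholog_map.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  for (nm in c("model_train", "target_train", "model_test", "target_test")) {
    write_expression_table(study[[nm]], paths[[nm]],
                           paths[[paste0(nm, "_labels")]])
  }
  readr::write_tsv(study$ortholog_map, paths[["ortholog_map"]],
                   progress = FALSE)
  readr::write_tsv(study$truth, paths[["truth"]], progress = FALSE)
  data_paths <- paths[names(paths) != "manifest"]
  manifest <- list(
    tool = paste0("ebtrans ", utils::packageVersion("ebtrans")),
    config = unclass(study$config),
    checksums = as.list(tools::md5sum(unname(data_paths)))
  )
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}
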