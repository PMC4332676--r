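#' Select genes from a translation result
#'
#' The two selection rules used in the concordance evaluations: all genes
#' with `p` below a threshold, or the `k` most significant genes. Top-`k`
#' ties on `p` are broken by larger `|t|`, then lexicographic `gene_id`, so
#' the selection is deterministic.
#'
#' @param results A translation results tibble (columns `gene_id`, `t`,
#'   `p`).
#' @param rule `"p_threshold"` or `"top_n"`.
#' @param theta p-value threshold for `rule = "p_threshold"`; default
#'   `0.05`.
#' @param k Number of genes for `rule = "top_n"`; default `500`.
#' @return Character vector of selected gene ids.
#' @export
select_genes <- function(results, rule = c("p_threshold", "top_n"),
                         theta = 0.05, k = 500) {
  rule <- match.arg(rule)
  if (rule == "p_threshold") {
    stopifnot(theta > 0, theta < 1)
    return(results$gene_id[results$p < theta])
  }
  stopifnot(k >= 1)
  if (k > nrow(results)) {
    warning("top_n k = ", k, " exceeds the ", nrow(results),
            "-gene universe; returning all genes", call. = FALSE)
    k <- nrow(results)
  }
  ord <- order(results$p, -abs(results$t), results$gene_id)
  results$gene_id[ord][seq_len(k)]
}

agreement_report <- function(n_selected, n_agree, selection, layer) {
  tibble::tibble(
    n_selected = n_selected,
    n_agree = n_agree,
    fraction = if (n_selected > 0) n_agree / n_selected else NA_real_,
    selection = selection,
    layer = layer
  )
}

#' Direction agreement of overall responses
#'
#' For a set of selected model-organism genes, the fraction whose direction
#' of change matches the orthologous target-side direction. A gene agrees
#' only when both directions are nonzero and equal; zero-direction genes
#' remain in the denominator as disagreements.
#'
#' @param selected Character vector of selected gene ids.
#' @param model_test,target_test Gene-stats tibbles (from
#'   [compute_gene_stats()] or a paired table) with columns `gene_id` and
#'   `direction`, for the model and target test experiments.
#' @param selection Label recorded in the report (free text).
#' @return One-row agreement tibble: `n_selected`, `n_agree`, `fraction`,
#'   `selection`, `layer`.
#' @export
overall_agreement <- function(selected, model_test, target_test,
                              selection = "p<0.05") {
  dm <- model_test$direction[match(selected, model_test$gene_id)]
  dt <- target_test$direction[match(selected, target_test$gene_id)]
  keep <- !is.na(dm) & !is.na(dt)
  dm <- dm[keep]
  dt <- dt[keep]
  agree <- dm != 0 & dt != 0 & dm == dt
  rep <- agreement_report(length(dm), sum(agree), selection, "overall")
  if (rep$n_selected == 0) {
    warning("empty selection: agreement fraction undefined", call. = FALSE)
  }
  rep
}

#' Direction agreement of experiment-specific responses
#'
#' A selected gene carries an experiment-specific response when its model
#' direction flips between the training and test experiments (both
#' directions nonzero). Such a gene agrees only when the target side shows
#' the same test direction as the model *and* itself flips relative to its
#' own training direction; the fraction is taken over the specific genes.
#'
#' @param selected Character vector of selected gene ids.
#' @param model_train,model_test,target_train,target_test Gene-stats
#'   tibbles with columns `gene_id` and `direction` (equivalently
#'   `sign(f)`).
#' @param selection Label recorded in the report.
#' @return One-row agreement tibble with `layer = "specific"`.
#' @export
specific_response_agreement <- function(selected, model_train, model_test,
                                        target_train, target_test,
                                        selection = "p<0.05") {
  d <- function(tab) tab$direction[match(selected, tab$gene_id)]
  mtr <- d(model_train); mte <- d(model_test)
  ttr <- d(target_train); tte <- d(target_test)
  keep <- !is.na(mtr) & !is.na(mte) & !is.na(ttr) & !is.na(tte)
  mtr <- mtr[keep]; mte <- mte[keep]; ttr <- ttr[keep]; tte <- tte[keep]
  specific <- mte != 0 & mtr != 0 & mte != mtr
  agree <- specific & tte == mte & tte != ttr
  agreement_report(sum(specific), sum(agree), selection, "specific")
}

#' One-sided Fisher enrichment of gene sets in a selection
#'
#' Over-representation p-value of each gene set in a selection, from the
#' hypergeometric upper tail of the 2x2 table (in-selection & in-set vs the
#' three complements within the universe). Set membership is intersected
#' with the universe first.
#'
#' @param selected Character vector, a subset of `universe`.
#' @param universe Character vector, the analysis gene universe.
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @return Tibble with columns `set_name`, `n_set` (members in universe),
#'   `n_overlap` (members selected), `p`.
#' @examples
#' sets <- list(hit = paste0("g", 1:10), miss = paste0("g", 90:99))
#' fisher_enrichment(paste0("g", 1:10), paste0("g", 1:100), sets)
#' @export
fisher_enrichment <- function(selected, universe, sets) {
  if (length(universe) == 0) {
    stop("configuration error: empty gene universe", call. = FALSE)
  }
  selected <- intersect(selected, universe)
  n_univ <- length(universe)
  n_sel <- length(selected)
  n_set <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  n_overlap <- vapply(sets, function(s) length(intersect(s, selected)), 0L)
  # P(X >= k) for X ~ Hypergeom(universe, set, selection)
  p <- stats::phyper(n_overlap - 1, n_set, n_univ - n_set, n_sel,
                     lower.tail = FALSE)
  tibble::tibble(
    set_name = names(sets),
    n_set = unname(n_set),
    n_overlap = unname(n_overlap),
    p = unname(p)
  )
}

#' Agreement of enriched biological contexts
#'
#' Splits each side's significant genes into activated (`f > 0`) and
#' suppressed (`f < 0`) lists, tests every gene set for over-representation
#' in each list with [fisher_enrichment()], and reports the fraction of
#' contexts enriched on the model side (per direction) that are also
#' enriched in the matching direction on the target side. Directions are
#' evaluated separately and pooled into one headline fraction; the
#' per-direction detail is kept in the `detail` attribute.
#'
#' @param model_results,target_results Translation results tibbles sharing
#'   a gene universe.
#' @param sets Named list of gene sets.
#' @param theta Significance threshold applied both to gene selection and
#'   to enrichment p-values; default `0.05`.
#' @return One-row agreement tibble with `layer = "context"`; attribute
#'   `detail` holds the per-direction counts.
#' @export
context_agreement <- function(model_results, target_results, sets,
                              theta = 0.05) {
  universe <- intersect(model_results$gene_id, target_results$gene_id)
  one_side <- function(res, dir) {
    sel <- res$gene_id[res$p < theta & sign(res$f) == dir]
    enr <- fisher_enrichment(sel, universe, sets)
    enr$set_name[enr$p < theta]
  }
  counts <- purrr::map_dfr(c(activated = 1, suppressed = -1), function(dir) {
    m_ctx <- one_side(model_results, dir)
    t_ctx <- one_side(target_results, dir)
    tibble::tibble(n_model = length(m_ctx),
                   n_common = length(intersect(m_ctx, t_ctx)))
  }, .id = "direction")
  rep <- agreement_report(sum(counts$n_model), sum(counts$n_common),
                          sprintf("p<%g", theta), "context")
  attr(rep, "detail") <- counts
  rep
}

#' Exclusion-baseline gene selection
#'
#' The alternative translation strategy that restricts attention to genes
#' significant in *both* species of the training pair: returns the test
#' genes significant at `theta` that were also significant in the model and
#' target training analyses. More stringent than pseudo-variance
#' penalization, at the cost of discarding many translatable genes.
#'
#' @param model_train,target_train,model_test Translation results tibbles
#'   on a shared universe (columns `gene_id`, `p`).
#' @param theta Significance threshold; default `0.05`.
#' @return Character vector of gene ids.
#' @export
exclusion_baseline <- function(model_train, target_train, model_test,
                               theta = 0.05) {
  sig <- function(res) res$gene_id[res$p < theta]
  common_train <- intersect(sig(model_train), sig(target_train))
  intersect(common_train, sig(model_test))
}

#' Rank correlation of fold changes between two experiments
#'
#' Spearman correlation of per-gene fold changes over the genes shared by
#' two gene-stats tables; the similarity measure used to characterise how
#' alike two experiments' genomic responses are.
#'
#' @param stats_a,stats_b Gene-stats tibbles with columns `gene_id`, `f`.
#' @return Spearman correlation coefficient; `NA` with a warning when
#'   either side is constant (correlation undefined).
#' @export
rank_correlation <- function(stats_a, stats_b) {
  shared <- intersect(stats_a$gene_id, stats_b$gene_id)
  if (length(shared) < 3) {
    stop("need at least 3 shared genes for a rank correlation",
         call. = FALSE)
  }
  fa <- stats_a$f[match(shared, stats_a$gene_id)]
  fb <- stats_b$f[match(shared, stats_b$gene_id)]
  if (length(unique(fa)) == 1 || length(unique(fb)) == 1) {
    warning("constant fold changes: rank correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(fa, fb, method = "spearman")
}
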